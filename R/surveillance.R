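# Hourly surveillance loop over a cohort: raise, deduplicate, triage and
# automatically terminate alerts; plus the seeded triage policy standing in
# for the pharmacist's relevance assessment, triage accounting, and
# JSON-Lines persistence of alert logs.

#' Seeded stochastic triage policy
#'
#' Models the pharmacist step of the alert pipeline: pending alerts are
#' reviewed with a per-tick probability (review latency), a reviewed alert
#' becomes an intervention message with a per-alert-number probability
#' (otherwise it is dismissed as not relevant), and each intervention's
#' outcome is drawn per category. All draws are governed by the policy seed,
#' so identical inputs give byte-identical logs. `mode = "always_intervene"`
#' is the degenerate deterministic policy used in validation runs: every
#' alert is reviewed at the first opportunity, always intervened, always
#' accepted.
#'
#' @param p_intervention probability that a reviewed alert becomes an
#'   intervention; scalar or length-12 vector indexed by alert number.
#'   Defaults reflect typical triage of the two categories (0.73 for
#'   missing-PPI alerts, 0.44 for the inappropriate-PPI alert).
#' @param p_accept named per-category probability that an intervention is
#'   accepted
#' @param p_unknown named per-category probability that an intervention's
#'   outcome cannot be assessed
#' @param p_review_per_tick probability a pending alert is reviewed at a
#'   given tick (default 1/8: mailbox checked about once per shift)
#' @param seed integer RNG seed
#' @param mode `"stochastic"` or `"always_intervene"`
#' @return object of class `triage_policy`
#' @export
triage_policy <- function(p_intervention = c(rep(0.73, 11), 0.44),
                          p_accept = c(MISSING_PPI = 0.73, INAPPROPRIATE_PPI = 0.34),
                          p_unknown = c(MISSING_PPI = 0.10, INAPPROPRIATE_PPI = 0.10),
                          p_review_per_tick = 1 / 8, seed = 1L,
                          mode = c("stochastic", "always_intervene")) {
  mode <- match.arg(mode)
  if (length(p_intervention) == 1L) p_intervention <- rep(p_intervention, 12)
  if (length(p_intervention) != 12L)
    ppi_stop("validation_error", "p_intervention must have length 1 or 12")
  probs <- c(p_intervention, p_accept, p_unknown, p_review_per_tick)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    ppi_stop("validation_error", "triage probabilities must lie in [0, 1]")
  if (mode == "always_intervene") {
    p_intervention <- rep(1, 12)
    p_accept[] <- 1; p_unknown[] <- 0; p_review_per_tick <- 1
  }
  structure(list(p_intervention = p_intervention, p_accept = p_accept,
                 p_unknown = p_unknown, p_review_per_tick = p_review_per_tick,
                 seed = as.integer(seed), mode = mode),
            class = "triage_policy")
}

empty_alert_log <- function() {
  data.frame(alert_id = character(), case_id = character(),
             alert_no = integer(), category = character(),
             raised_at = as.POSIXct(character(), tz = "UTC"),
             status = character(),
             status_changed_at = as.POSIXct(character(), tz = "UTC"),
             intervention_sent = logical(),
             intervention_at = as.POSIXct(character(), tz = "UTC"),
             intervention_outcome = character(),
             snap_ppi_status = character(), snap_factor_count = integer(),
             stringsAsFactors = FALSE)
}

#' Run batch surveillance over a cohort
#'
#' Replays the surveillance engine over a fixed dataset: at every tick
#' (`t0 + k * step_hours`, mirroring the hourly review of patient files),
#' each included in-hospital case is profiled, candidate alerts are
#' computed and suppressed, new alerts are raised as `PENDING` (deduplicated
#' against any non-resolved alert of the same case and alert number), the
#' triage policy is applied to pending alerts raised at earlier ticks, and
#' open alerts whose trigger predicate no longer holds -- or whose case has
#' been discharged -- are automatically terminated (`RESOLVED`). Alerts
#' dismissed as `NOT_RELEVANT` are terminal and are not re-raised for the
#' same case. Events between ticks are observed at the next tick.
#'
#' @inheritParams risk_profile
#' @param policy a [triage_policy]
#' @param t0,t1 surveillance window; defaults cover the whole dataset
#'   (earliest admission to latest discharge plus one step)
#' @param step_hours tick spacing in hours (default 1)
#' @param include_excluded also monitor cases flagged excluded from analysis
#' @return data frame of class `alert_log`, append-only in raise order, with
#'   lifecycle fields and a trigger snapshot per alert; the monitored case
#'   ids are attached as attribute `case_ids`
#' @export
run_surveillance <- function(ds, kb, thresholds = risk_thresholds(),
                             policy = triage_policy(), t0 = NULL, t1 = NULL,
                             step_hours = 1, replicate_bug_on_demand = FALSE,
                             include_excluded = FALSE) {
  stopifnot(inherits(policy, "triage_policy"))
  ann <- annotate_cohort(ds, kb, thresholds)
  cases <- ann$cases
  if (!include_excluded) cases <- cases[!cases$excluded, , drop = FALSE]
  mk_log <- function(df) {
    df <- df[order(df$raised_at, df$case_id, df$alert_no), , drop = FALSE]
    rownames(df) <- NULL
    structure(df, class = c("alert_log", "data.frame"),
              case_ids = cases$case_id)
  }
  if (!nrow(cases)) return(mk_log(empty_alert_log()))
  t0 <- if (is.null(t0)) min(cases$adm_n) else as.numeric(parse_ts(t0))
  t1_default <- max(cases$dis_n[is.finite(cases$dis_n)], cases$adm_n) + hours(step_hours)
  t1 <- if (is.null(t1)) t1_default else as.numeric(parse_ts(t1))
  if (t0 >= t1) ppi_stop("validation_error", "t0 must precede t1")
  step <- hours(step_hours)
  ticks <- seq(t0, t1, by = step)

  log <- list()       # one list-row per alert, updated in place
  open_idx <- integer()   # indices into log with status PENDING/INTERVENTION
  seen <- character() # "case\ralert_no" keys with a non-RESOLVED alert
  n_alert <- 0L

  with_private_seed(policy$seed, {
    for (t in ticks) {
      in_stay <- cases$adm_n <= t & t < cases$dis_n
      ids <- cases$case_id[in_stay]
      fl <- snapshot_flags(ann, t, ids, replicate_bug_on_demand)
      cand <- evaluate_flags(fl, thresholds$multi_factor_min)
      names(cand) <- ids
      # --- automatic termination ---------------------------------------
      if (length(open_idx)) {
        drop <- logical(length(open_idx))
        for (j in seq_along(open_idx)) {
          a <- log[[open_idx[j]]]
          still <- !is.na(match(a$case_id, ids)) &&
            a$alert_no %in% cand[[a$case_id]]
          if (!still) {
            a$status <- "RESOLVED"
            a$status_changed_at <- t
            log[[open_idx[j]]] <- a
            seen <- setdiff(seen, paste(a$case_id, a$alert_no, sep = "\r"))
            drop[j] <- TRUE
          }
        }
        open_idx <- open_idx[!drop]
      }
      # --- triage of pending alerts raised at earlier ticks -------------
      for (j in open_idx) {
        a <- log[[j]]
        if (a$status != "PENDING" || a$raised_at >= t) next
        if (runif(1) >= policy$p_review_per_tick) next
        if (runif(1) < policy$p_intervention[a$alert_no]) {
          a$status <- "INTERVENTION"
          a$intervention_sent <- TRUE
          a$intervention_at <- t
          u <- runif(1)
          pa <- policy$p_accept[[a$category]]
          pu <- policy$p_unknown[[a$category]]
          a$intervention_outcome <- if (u < pa) "ACCEPTED"
            else if (u < pa + pu) "UNKNOWN" else "NOT_ACCEPTED"
        } else {
          a$status <- "NOT_RELEVANT"
        }
        a$status_changed_at <- t
        log[[j]] <- a
      }
      open_idx <- open_idx[vapply(log[open_idx], function(a)
        a$status %in% c("PENDING", "INTERVENTION"), TRUE)]
      # --- raise new alerts (after suppression, deduplicated) -----------
      # an open missing-PPI alert suppresses raising any other one for the
      # same case, keeping at most one open missing-PPI alert per case
      open_missing <- unique(vapply(log[open_idx], function(a)
        if (a$alert_no <= 11L) a$case_id else NA_character_, ""))
      for (cid in ids) {
        for (no in suppress_alerts(cand[[cid]])) {
          key <- paste(cid, no, sep = "\r")
          if (key %in% seen) next
          if (no <= 11L && cid %in% open_missing) next
          n_alert <- n_alert + 1L
          i <- match(cid, ids)
          log[[n_alert]] <- list(
            alert_id = sprintf("A%05d", n_alert), case_id = cid,
            alert_no = as.integer(no), category = alert_category(no),
            raised_at = t, status = "PENDING", status_changed_at = t,
            intervention_sent = FALSE, intervention_at = NA_real_,
            intervention_outcome = "n/a",
            snap_ppi_status = fl$ppi_status[i],
            snap_factor_count = as.integer(fl$factor_count[i]))
          open_idx <- c(open_idx, n_alert)
          seen <- c(seen, key)
        }
      }
    }
    # close out alerts of cases discharged within the window
    for (j in open_idx) {
      a <- log[[j]]
      dis <- cases$dis_n[match(a$case_id, cases$case_id)]
      if (is.finite(dis) && dis <= t1) {
        a$status <- "RESOLVED"
        a$status_changed_at <- min(dis, t1)
        log[[j]] <- a
      }
    }
  })

  if (!length(log)) return(mk_log(empty_alert_log()))
  df <- do.call(rbind, lapply(log, function(a) as.data.frame(a, stringsAsFactors = FALSE)))
  df$raised_at <- as.POSIXct(df$raised_at, origin = "1970-01-01", tz = "UTC")
  df$status_changed_at <- as.POSIXct(df$status_changed_at, origin = "1970-01-01", tz = "UTC")
  df$intervention_at <- as.POSIXct(df$intervention_at, origin = "1970-01-01", tz = "UTC")
  mk_log(df)
}

#' Triage and acceptance accounting of an alert log
#'
#' Tallies, per category and overall, how alerts ended: intervention message
#' sent, dismissed as not relevant, automatically resolved without an
#' intervention, or still pending; and the acceptance rate of interventions
#' (accepted divided by all intervention messages sent; `NA` when no
#' intervention was sent).
#'
#' @param log an `alert_log`
#' @return object of class `triage_summary`: list with `by_category`,
#'   `by_alert_no` and `overall` data frames
#' @export
triage_summary <- function(log) {
  tally <- function(df) {
    interventions <- sum(df$intervention_sent)
    accepted <- sum(df$intervention_outcome == "ACCEPTED")
    unknown <- sum(df$intervention_outcome == "UNKNOWN")
    data.frame(
      n_alerts = nrow(df),
      interventions = interventions,
      not_relevant = sum(df$status == "NOT_RELEVANT"),
      resolved_without_intervention = sum(df$status == "RESOLVED" & !df$intervention_sent),
      pending = sum(df$status == "PENDING"),
      accepted = accepted,
      not_accepted = sum(df$intervention_outcome == "NOT_ACCEPTED"),
      unknown = unknown,
      acceptance_rate = if (interventions > 0) accepted / interventions else NA_real_,
      unknown_rate = if (interventions > 0) unknown / interventions else NA_real_)
  }
  cats <- c("MISSING_PPI", "INAPPROPRIATE_PPI")
  by_cat <- do.call(rbind, lapply(cats, function(cc) {
    cbind(category = cc, tally(log[log$category == cc, , drop = FALSE]))
  }))
  defs <- alert_definitions()
  by_no <- do.call(rbind, lapply(defs$alert_no, function(no) {
    cbind(alert_no = no, tally(log[log$alert_no == no, , drop = FALSE]))
  }))
  structure(list(by_category = by_cat, by_alert_no = by_no,
                 overall = tally(log)),
            class = "triage_summary")
}

#' @export
print.triage_summary <- function(x, ...) {
  cat("Alert triage summary\n")
  cat(sprintf("  total alerts: %d | interventions: %d | acceptance rate: %s\n",
              x$overall$n_alerts, x$overall$interventions,
              if (is.na(x$overall$acceptance_rate)) "n/a"
              else sprintf("%.1f%%", 100 * x$overall$acceptance_rate)))
  for (i in seq_len(nrow(x$by_category))) {
    r <- x$by_category[i, ]
    cat(sprintf("  %-17s alerts %4d | intervention %4d | not relevant %4d | auto-resolved %4d | accepted %s\n",
                r$category, r$n_alerts, r$interventions, r$not_relevant,
                r$resolved_without_intervention,
                if (is.na(r$acceptance_rate)) "n/a"
                else sprintf("%.0f%%", 100 * r$acceptance_rate)))
  }
  invisible(x)
}

ALERT_LOG_FIELDS <- c("alert_id", "case_id", "alert_no", "category",
                      "raised_at", "status", "status_changed_at",
                      "intervention_sent", "intervention_at",
                      "intervention_outcome", "snap_ppi_status",
                      "snap_factor_count")

#' Write / read an alert log as JSON-Lines
#'
#' One alert per line with a stable field order, so logs diff cleanly.
#'
#' @param log an `alert_log`
#' @param path file path
#' @return `write_alert_log` the path invisibly; `read_alert_log` an
#'   `alert_log`
#' @export
write_alert_log <- function(log, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    row <- as.list(log[i, ALERT_LOG_FIELDS])
    for (nm in c("raised_at", "status_changed_at", "intervention_at"))
      row[[nm]] <- if (is.na(row[[nm]])) NULL else format_ts(row[[nm]])
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_alert_log
#' @export
read_alert_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(structure(empty_alert_log(),
                                       class = c("alert_log", "data.frame")))
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    for (nm in ALERT_LOG_FIELDS) if (is.null(x[[nm]])) x[[nm]] <- NA
    as.data.frame(x[ALERT_LOG_FIELDS], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  for (nm in c("raised_at", "status_changed_at", "intervention_at"))
    df[[nm]] <- parse_ts(df[[nm]])
  df$alert_no <- as.integer(df$alert_no)
  df$snap_factor_count <- as.integer(df$snap_factor_count)
  df$intervention_sent <- as.logical(df$intervention_sent)
  structure(df, class = c("alert_log", "data.frame"))
}
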