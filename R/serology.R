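#' Seropositivity thresholds and responder rules
#'
#' Per-vaccine seropositivity cut-offs (titer strictly above the cut-off
#' counts as seropositive), the fold-rise threshold defining a response
#' (inclusive: a 2-fold rise is still a response), the number of responding
#' antigens required for full pneumococcal-conjugate (PCV13) protection, and
#' the pre-immunization tetanus titer above which antibody is annotated as
#' likely maternally derived.
#'
#' @param cutoffs `data.frame(vaccine, cutoff, units)`; defaults cover HepB
#'   (0.8 mIU/mL), diphtheria and tetanus toxoid (0.01 IU/mL), Hib
#'   (0.15 ug/mL), pertussis antigens (25 EU/mL), PCV13 (0.35 ug/mL) and
#'   rotavirus IgA (20 U/mL).
#' @param fold_threshold Fold rise counted as a response (default 2,
#'   boundary inclusive).
#' @param pcv13_min_antigens Responding/seropositive antigens required for
#'   full PCV13 protection (default 4).
#' @param maternal_tetanus_pre Pre titer (IU/mL) above which tetanus antibody
#'   is annotated maternal (default 0.1).
#' @return List of class `sero_thresholds`.
#' @export
sero_thresholds <- function(cutoffs = NULL, fold_threshold = 2,
                            pcv13_min_antigens = 4,
                            maternal_tetanus_pre = 0.1) {
  if (is.null(cutoffs)) {
    cutoffs <- data.frame(
      vaccine = c("HepB", "Diphtheria", "Tetanus", "Hib", "Pertussis",
                  "PCV13", "Rotavirus"),
      cutoff  = c(0.8, 0.01, 0.01, 0.15, 25, 0.35, 20),
      units   = c("mIU/mL", "IU/mL", "IU/mL", "ug/mL", "EU/mL",
                  "ug/mL", "U/mL"),
      stringsAsFactors = FALSE)
  }
  if (any(cutoffs$cutoff <= 0)) stopf("cut-offs must be > 0")
  thr <- list(cutoffs = cutoffs, fold_threshold = fold_threshold,
              pcv13_min_antigens = pcv13_min_antigens,
              maternal_tetanus_pre = maternal_tetanus_pre)
  class(thr) <- "sero_thresholds"
  thr
}

cutoff_for <- function(thr, vaccine, row_id = NULL) {
  i <- match(vaccine, thr$cutoffs$vaccine)
  if (is.na(i)) stopf("no cut-off configured for vaccine '%s'", vaccine)
  thr$cutoffs[i, ]
}

check_units <- function(titers, thr) {
  for (i in seq_len(nrow(titers))) {
    co <- cutoff_for(thr, titers$vaccine[i])
    if (!identical(titers$units[i], co$units))
      stopf("unit mismatch for %s/%s (row %d): got '%s', thresholds assume '%s'",
            titers$infant[i], titers$antigen[i], i, titers$units[i], co$units)
  }
  invisible(TRUE)
}

#' Seroprotection calls per infant and vaccine
#'
#' An antigen is seropositive when its titer strictly exceeds the vaccine's
#' cut-off. Single-antigen vaccines are protective iff their antigen is
#' seropositive; PCV13 iff at least `pcv13_min_antigens` antigens are; any
#' other multi-antigen vaccine (e.g. the toxoid components of DTaP) iff all
#' its antigens are. Unit strings are checked verbatim against the
#' thresholds.
#'
#' @param titers Serology table (see [read_serology()]).
#' @param thr [sero_thresholds()].
#' @param timepoint Which records to evaluate (default `"post"`).
#' @return `data.frame` with `infant`, `vaccine`, `n_antigens`,
#'   `n_seropositive`, `protected`.
#' @export
seroprotection <- function(titers, thr = sero_thresholds(), timepoint = "post") {
  tt <- titers[titers$timepoint == timepoint, , drop = FALSE]
  check_units(tt, thr)
  out <- list()
  for (inf in unique(tt$infant)) {
    for (vx in unique(tt$vaccine[tt$infant == inf])) {
      d <- tt[tt$infant == inf & tt$vaccine == vx, , drop = FALSE]
      co <- cutoff_for(thr, vx)
      pos <- d$value > co$cutoff
      protected <- if (vx == "PCV13") sum(pos) >= thr$pcv13_min_antigens
                   else all(pos)
      out[[length(out) + 1L]] <- data.frame(
        infant = inf, vaccine = vx, n_antigens = nrow(d),
        n_seropositive = sum(pos), protected = protected,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Pre/post fold responses per infant and antigen
#'
#' `fold = post / pre` (infinite when pre is 0 and post positive; 1 when both
#' are 0). An antigen responds when the fold is at least the configured
#' threshold (inclusive) or when it seroconverts across the vaccine's
#' cut-off. Records without a pre/post pair are flagged unevaluable.
#' Tetanus records with pre titer above `maternal_tetanus_pre` are annotated
#' `maternal_ab` (pre-existing antibody of likely maternal origin).
#'
#' @param titers Serology table with `pre` and `post` records.
#' @param thr [sero_thresholds()].
#' @return `data.frame` with `infant`, `vaccine`, `antigen`, `pre`, `post`,
#'   `fold`, `seroconverted`, `response`, `evaluable`, `maternal_ab`.
#' @export
fold_response <- function(titers, thr = sero_thresholds()) {
  check_units(titers, thr)
  keys <- unique(titers[c("infant", "vaccine", "antigen")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    d <- titers[titers$infant == keys$infant[i] &
                titers$antigen == keys$antigen[i] &
                titers$vaccine == keys$vaccine[i], , drop = FALSE]
    pre <- d$value[d$timepoint == "pre"]
    post <- d$value[d$timepoint == "post"]
    co <- cutoff_for(thr, keys$vaccine[i])
    if (length(pre) != 1 || length(post) != 1) {
      out[[i]] <- data.frame(keys[i, ], pre = NA_real_, post = NA_real_,
                             fold = NA_real_, seroconverted = NA,
                             response = NA, evaluable = FALSE,
                             maternal_ab = NA, stringsAsFactors = FALSE)
      next
    }
    fold <- if (pre == 0) { if (post > 0) Inf else 1 } else post / pre
    seroconv <- pre <= co$cutoff && post > co$cutoff
    out[[i]] <- data.frame(
      keys[i, ], pre = pre, post = post, fold = fold,
      seroconverted = seroconv,
      response = fold >= thr$fold_threshold || seroconv,
      evaluable = TRUE,
      maternal_ab = keys$vaccine[i] == "Tetanus" && pre > thr$maternal_tetanus_pre,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Per-vaccine response levels
#'
#' Summarizes [fold_response()] output into `full` / `partial` / `none` per
#' (infant, vaccine): PCV13 is full with at least `pcv13_min_antigens`
#' responding antigens, partial with 1 to that minus one, none with 0; other
#' multi-antigen vaccines are full when all antigens respond and partial when
#' some do; single-antigen vaccines are full iff the antigen responds.
#' Vaccines with no evaluable antigen get level `NA`.
#'
#' @param folds Output of [fold_response()].
#' @param thr [sero_thresholds()].
#' @return `data.frame` with `infant`, `vaccine`, `n_antigens`, `n_respond`,
#'   `level`.
#' @export
vaccine_response_levels <- function(folds, thr = sero_thresholds()) {
  out <- list()
  for (inf in unique(folds$infant)) {
    for (vx in unique(folds$vaccine[folds$infant == inf])) {
      d <- folds[folds$infant == inf & folds$vaccine == vx, , drop = FALSE]
      ev <- d[d$evaluable, , drop = FALSE]
      n_resp <- sum(ev$response)
      level <- if (!nrow(ev)) NA_character_
      else if (vx == "PCV13") {
        if (n_resp >= thr$pcv13_min_antigens) "full"
        else if (n_resp >= 1) "partial" else "none"
      } else if (nrow(ev) > 1) {
        if (n_resp == nrow(ev)) "full" else if (n_resp >= 1) "partial" else "none"
      } else if (n_resp == 1) "full" else "none"
      out[[length(out) + 1L]] <- data.frame(
        infant = inf, vaccine = vx, n_antigens = nrow(d), n_respond = n_resp,
        level = level, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Responder ranking rule table
#'
#' The default reproduces the breadth-of-response ranking: Best responders
#' respond fully to at least `best_min_full` vaccines; Good responders
#' respond fully to at least `good_min_full` and partially to at least
#' `good_min_partial` more; everyone else is a Weak responder. Infants with
#' fewer than `min_vaccines` evaluable vaccines are flagged as having
#' insufficient data.
#' @param best_min_full,good_min_full,good_min_partial,min_vaccines Rule
#'   parameters.
#' @return List of class `responder_rule`.
#' @export
responder_rule <- function(best_min_full = 4, good_min_full = 2,
                           good_min_partial = 1, min_vaccines = 3) {
  r <- list(best_min_full = best_min_full, good_min_full = good_min_full,
            good_min_partial = good_min_partial, min_vaccines = min_vaccines)
  class(r) <- "responder_rule"
  r
}

#' Rank infants into Best/Good/Weak responder classes
#'
#' Applies a [responder_rule()] to per-vaccine response levels. Raising any
#' titer can only move levels upward, so the ranking is monotone in the
#' underlying titers.
#'
#' @param levels Output of [vaccine_response_levels()].
#' @param rule [responder_rule()].
#' @return `data.frame` with `infant`, `n_full`, `n_partial`, `n_evaluable`,
#'   `class` (`Best-R`/`Good-R`/`Weak-R`, `NA` when insufficient),
#'   `insufficient_data`.
#' @export
rank_responders <- function(levels, rule = responder_rule()) {
  out <- list()
  for (inf in unique(levels$infant)) {
    d <- levels[levels$infant == inf, , drop = FALSE]
    ev <- d[!is.na(d$level), , drop = FALSE]
    n_full <- sum(ev$level == "full")
    n_part <- sum(ev$level == "partial")
    insufficient <- nrow(ev) < rule$min_vaccines
    cls <- if (insufficient) NA_character_
    else if (n_full >= rule$best_min_full) "Best-R"
    else if (n_full >= rule$good_min_full && n_part >= rule$good_min_partial) "Good-R"
    else "Weak-R"
    out[[length(out) + 1L]] <- data.frame(
      infant = inf, n_full = n_full, n_partial = n_part,
      n_evaluable = nrow(ev), class = cls,
      insufficient_data = insufficient, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Worked-example response profiles for a five-infant cohort
#'
#' Per-vaccine response levels for five 2-month-old infants with
#' heterogeneous primary vaccine responses: every infant boosts hepatitis B;
#' tetanus antibody (maternally derived) fails to rise in all; only one
#' infant responds to diphtheria; pneumococcal-conjugate breadth ranges from
#' 0 to 10 of 13 antigens; rotavirus IgA responds in four of five. Under the
#' default [responder_rule()] this profile yields one Best, two Good and two
#' Weak responders.
#'
#' @return `data.frame` in the format of [vaccine_response_levels()].
#' @export
example_response_profiles <- function() {
  lv <- function(infant, vaccine, n_antigens, n_respond, level)
    data.frame(infant = infant, vaccine = vaccine, n_antigens = n_antigens,
               n_respond = n_respond, level = level, stringsAsFactors = FALSE)
  rbind(
    lv("I1", "HepB", 1, 1, "full"), lv("I1", "Diphtheria", 1, 0, "none"),
    lv("I1", "Tetanus", 1, 0, "none"), lv("I1", "PCV13", 13, 1, "partial"),
    lv("I1", "Rotavirus", 1, 1, "full"),
    lv("I2", "HepB", 1, 1, "full"), lv("I2", "Diphtheria", 1, 0, "none"),
    lv("I2", "Tetanus", 1, 0, "none"), lv("I2", "PCV13", 13, 2, "partial"),
    lv("I2", "Rotavirus", 1, 1, "full"),
    lv("I4", "HepB", 1, 1, "full"), lv("I4", "Diphtheria", 1, 0, "none"),
    lv("I4", "Tetanus", 1, 0, "none"), lv("I4", "PCV13", 13, 0, "none"),
    lv("I4", "Rotavirus", 1, 1, "full"),
    lv("I5", "HepB", 1, 1, "full"), lv("I5", "Diphtheria", 1, 0, "none"),
    lv("I5", "Tetanus", 1, 0, "none"), lv("I5", "PCV13", 13, 3, "partial"),
    lv("I5", "Rotavirus", 1, 0, "none"),
    lv("I6", "HepB", 1, 1, "full"), lv("I6", "Diphtheria", 1, 1, "full"),
    lv("I6", "Tetanus", 1, 0, "none"), lv("I6", "PCV13", 13, 10, "full"),
    lv("I6", "Rotavirus", 1, 1, "full"))
}
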