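#' @title Antibody response: MFC, scaling and responder classes
#' @description The response metric is the maximum fold change (MFC): the
#'   largest day-28 (+/- 2 days) over pre-vaccination titer ratio across the
#'   vaccine's strains. MFC is z-scaled within each vaccine for cross-vaccine
#'   displays, and participants are classed per study as high (MFC at or
#'   above the study's 70th percentile), low (at or below the 30th) or
#'   moderate (strictly between), using type-7 empirical quantiles.
#' @name response
NULL

validate_titers <- function(titers) {
  need <- c("participant_id", "study_id", "vaccine", "strain", "day", "titer")
  missing.cols <- setdiff(need, names(titers))
  if (length(missing.cols)) {
    stop("titer table missing column(s): ", paste(missing.cols, collapse = ", "))
  }
  if (any(titers$titer <= 0)) stop("titers must be > 0")
  key <- paste(titers$participant_id, titers$strain, titers$day)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, strain, day) titer row(s)")
  }
  invisible(titers)
}

#' Maximum fold change of antibody titers
#'
#' Per strain, the fold change is the in-window post-vaccination titer
#' (nearest `target_day`; ties broken toward the later day) over the
#' pre-vaccination titer (day 0 preferred, day -7 fallback); the MFC is the
#' maximum over strains. Participants lacking a qualifying strain are
#' omitted with a message.
#'
#' @param titers titer table with columns participant_id, study_id, vaccine,
#'   strain, day, titer (assay optional).
#' @param target_day post-vaccination target day (default 28).
#' @param window half-width of the day window (default 2, i.e. 26..30).
#' @return data.frame of class `response_table`: participant_id, study_id,
#'   vaccine, mfc, log2_mfc, day_used.
#' @export
compute_mfc <- function(titers, target_day = 28L, window = 2L) {
  validate_titers(titers)
  out <- lapply(split(titers, titers$participant_id), function(d) {
    fcs <- c(); day.used <- NA_integer_
    for (s in unique(d$strain)) {
      ds <- d[d$strain == s, , drop = FALSE]
      base <- ds[ds$day == 0L, , drop = FALSE]
      if (!nrow(base)) base <- ds[ds$day == -7L, , drop = FALSE]
      post <- ds[abs(ds$day - target_day) <= window & ds$day > 0L, ,
                 drop = FALSE]
      if (!nrow(base) || !nrow(post)) next
      # nearest target day; tie -> later day
      post <- post[order(abs(post$day - target_day), -post$day), ,
                   drop = FALSE]
      fcs <- c(fcs, post$titer[1] / base$titer[1])
      day.used <- post$day[1]
    }
    if (!length(fcs)) return(NULL)
    data.frame(participant_id = d$participant_id[1],
               study_id = d$study_id[1], vaccine = d$vaccine[1],
               mfc = max(fcs), log2_mfc = log2(max(fcs)),
               day_used = day.used, stringsAsFactors = FALSE)
  })
  dropped <- names(out)[vapply(out, is.null, logical(1))]
  if (length(dropped)) {
    message("compute_mfc: omitted ", length(dropped),
            " participant(s) without a qualifying strain: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("response_table", "data.frame")
  res
}

#' Scale the MFC within each vaccine
#'
#' `scaled_mfc = (log2_mfc - mean_vaccine) / sd_vaccine`, so each vaccine's
#' scaled values have mean 0 and sd 1. A zero within-vaccine sd yields scaled
#' values of 0 with a warning; single-participant vaccines get `NA` with a
#' warning.
#'
#' @param responses a `response_table` from [compute_mfc()].
#' @return The table with a `scaled_mfc` column added.
#' @export
scale_mfc <- function(responses) {
  responses$scaled_mfc <- NA_real_
  for (v in unique(responses$vaccine)) {
    i <- responses$vaccine == v
    if (sum(i) < 2L) {
      warning("vaccine '", v, "' has a single participant; scaled_mfc is NA")
      next
    }
    s <- stats::sd(responses$log2_mfc[i])
    if (s == 0) {
      warning("vaccine '", v, "' has zero MFC variance; scaled_mfc set to 0")
      responses$scaled_mfc[i] <- 0
    } else {
      responses$scaled_mfc[i] <-
        (responses$log2_mfc[i] - mean(responses$log2_mfc[i])) / s
    }
  }
  responses
}

#' Per-study high/moderate/low responder classes
#'
#' Within each study, the 30th and 70th type-7 percentiles of the MFC define
#' low (MFC <= p30) and high (MFC >= p70) responders; everyone strictly
#' between is moderate. A participant satisfying both bounds (possible only
#' when p30 = p70, e.g. all MFCs equal) is moderate. Studies with fewer than
#' `min_n` participants are all moderate with a warning.
#'
#' @param responses a `response_table`.
#' @param min_n minimum participants per study for discretization (default 3).
#' @return The table with a `responder` column (`low`/`moderate`/`high`).
#' @export
discretize_responders <- function(responses, min_n = 3L) {
  responses$responder <- "moderate"
  for (st in unique(responses$study_id)) {
    i <- which(responses$study_id == st)
    if (length(i) < min_n) {
      warning("study '", st, "' has fewer than ", min_n,
              " participants; all moderate")
      next
    }
    q <- stats::quantile(responses$mfc[i], probs = c(0.30, 0.70), type = 7,
                         names = FALSE)
    hi <- responses$mfc[i] >= q[2]
    lo <- responses$mfc[i] <= q[1]
    responses$responder[i][hi & !lo] <- "high"
    responses$responder[i][lo & !hi] <- "low"
  }
  responses
}
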