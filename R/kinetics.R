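#' @title Endotype-stratified post-vaccination kinetics
#' @description Per-participant changes of superset SLEA scores from the
#'   pre-vaccination baseline (day 0 preferred, day -7 fallback) at binned
#'   post-vaccination days, compared between endotypes with two-sided
#'   Wilcoxon rank-sum tests (effect = difference of group medians) and
#'   Benjamini-Hochberg correction across all superset x bin x pair tests.
#' @name kinetics
NULL

#' Default post-vaccination day bins
#'
#' Centers 1, 3, 7, 14 with tolerance +/- 1 day for bins 1 and 3 and +/- 2
#' for 7 and 14, plus an open `"21+"` bin for day >= 21. A sample day is
#' assigned to the bin with the nearest center (ties toward the later bin)
#' and kept only if within that bin's tolerance.
#'
#' @return data.frame with columns name, center, tol.
#' @export
default_day_bins <- function() {
  data.frame(name = c("1", "3", "7", "14", "21+"),
             center = c(1, 3, 7, 14, 21),
             tol = c(1, 1, 2, 2, Inf),
             stringsAsFactors = FALSE)
}

assign_day_bin <- function(day, bins) {
  vapply(day, function(d) {
    if (d <= 0) return(NA_character_)
    if (is.infinite(bins$tol[nrow(bins)]) && d >= bins$center[nrow(bins)]) {
      return(bins$name[nrow(bins)])
    }
    dist <- abs(d - bins$center)
    i <- which(dist == min(dist))
    i <- i[length(i)]  # tie -> later bin
    if (dist[i] <= bins$tol[i]) bins$name[i] else NA_character_
  }, character(1))
}

#' Per-participant kinetic deltas of superset scores
#'
#' `delta(participant, superset, bin) = score(post sample in bin) -
#' score(pre sample)`; the pre sample is day 0 (day -7 fallback); with
#' multiple post samples in a bin, the one nearest the bin center is used
#' (tie toward the later day). Participants lacking a pre/post pair are
#' omitted with a message.
#'
#' @param slea a `slea_matrix` of superset scores over all samples.
#' @param samples sample metadata table.
#' @param endotypes data.frame (participant_id, endotype), e.g. from
#'   [participant_endotypes()].
#' @param day_bins bin table as from [default_day_bins()].
#' @return Long data.frame: participant_id, endotype, superset, day_bin,
#'   day, delta.
#' @export
compute_deltas <- function(slea, samples, endotypes,
                           day_bins = default_day_bins()) {
  z <- slea_z(slea)
  samples <- samples[samples$sample_id %in% colnames(z), , drop = FALSE]
  samples$bin <- assign_day_bin(samples$day, day_bins)
  out <- list(); omitted <- character(0)
  for (pid in unique(samples$participant_id)) {
    d <- samples[samples$participant_id == pid, , drop = FALSE]
    pre <- d[d$day == 0L, , drop = FALSE]
    if (!nrow(pre)) pre <- d[d$day == -7L, , drop = FALSE]
    post <- d[!is.na(d$bin), , drop = FALSE]
    if (!nrow(pre) || !nrow(post)) { omitted <- c(omitted, pid); next }
    pre.id <- pre$sample_id[1]
    et <- endotypes$endotype[match(pid, endotypes$participant_id)]
    for (b in unique(post$bin)) {
      pb <- post[post$bin == b, , drop = FALSE]
      ctr <- day_bins$center[day_bins$name == b]
      pb <- pb[order(abs(pb$day - ctr), -pb$day), , drop = FALSE]
      delta <- z[, pb$sample_id[1]] - z[, pre.id]
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, endotype = et,
        superset = rownames(z), day_bin = b, day = pb$day[1],
        delta = unname(delta), stringsAsFactors = FALSE)
    }
  }
  if (length(omitted)) {
    message("compute_deltas: omitted ", length(omitted),
            " participant(s) without a pre/post pair")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare kinetic deltas between endotypes
#'
#' Two-sided Wilcoxon rank-sum test per (superset, day bin, endotype pair) on
#' participant deltas; effect = median(group A) - median(group B); BH
#' correction across all tests in the table. Comparisons with an empty (or
#' undersized) group are skipped with a message.
#'
#' @param deltas long table from [compute_deltas()].
#' @param pairs list of 2-vectors of endotype labels; defaults to all three
#'   pairs of `inflam.hi`/`inflam.mid`/`inflam.lo`.
#' @param min_n minimum participants per group (default 2).
#' @return List with `medians` (per superset x bin x endotype: n, median
#'   delta) and `comparisons` (superset, day_bin, group_a, group_b, effect,
#'   wilcoxon_p, bh_adjusted_p).
#' @export
compare_endotypes <- function(deltas,
                              pairs = list(c("inflam.hi", "inflam.lo"),
                                           c("inflam.hi", "inflam.mid"),
                                           c("inflam.mid", "inflam.lo")),
                              min_n = 2L) {
  med <- stats::aggregate(delta ~ superset + day_bin + endotype, deltas,
                          stats::median)
  names(med)[names(med) == "delta"] <- "median_delta"
  n <- stats::aggregate(delta ~ superset + day_bin + endotype, deltas, length)
  med$n_participants <- n$delta

  rows <- list(); skipped <- 0L
  for (ss in unique(deltas$superset)) {
    for (b in unique(deltas$day_bin)) {
      d <- deltas[deltas$superset == ss & deltas$day_bin == b, , drop = FALSE]
      for (pr in pairs) {
        a <- d$delta[d$endotype == pr[1]]
        bb <- d$delta[d$endotype == pr[2]]
        if (length(a) < min_n || length(bb) < min_n) {
          skipped <- skipped + 1L; next
        }
        wt <- wilcoxon_rank_sum(a, bb)
        rows[[length(rows) + 1L]] <- data.frame(
          superset = ss, day_bin = b, group_a = pr[1], group_b = pr[2],
          n_a = length(a), n_b = length(bb),
          effect = stats::median(a) - stats::median(bb),
          wilcoxon_p = wt$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped) {
    message("compare_endotypes: skipped ", skipped,
            " comparison(s) with a group below ", min_n, " participants")
  }
  comp <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(comp)) comp$bh_adjusted_p <- bh_adjust(comp$wilcoxon_p)
  list(medians = med, comparisons = comp)
}
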