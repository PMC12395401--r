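# Maturity-group classification and timing-tempo summaries.
#
# Maturational timing is indexed by the individual age at peak height
# velocity (APHV).  The primary rule is distribution-based: within each
# sex, subjects below the 16th percentile of APHV are early maturers,
# above the 84th late maturers, and average in between.  A mean +/- 1 SD
# variant is available behind a switch (under normality the two nearly
# coincide).

#' Classify maturity status from individual APHV
#'
#' @param aphv Named numeric vector of per-subject APHV point estimates
#'   (posterior means), one sex at a time.
#' @param percentiles Lower/upper percentile thresholds (default 16/84).
#' @param method `"percentile"` (primary) or `"sd"` (mean +/- 1 SD).
#' @param min_n Smallest sample the classification accepts (percentile
#'   thresholds are meaningless on a handful of subjects).
#' @return A `maturity_classification`: data frame `id`, `aphv`, `label`
#'   with thresholds in attributes.
#' @export
classify_maturity <- function(aphv, percentiles = c(16, 84),
                              method = c("percentile", "sd"), min_n = 10) {
  method <- match.arg(method)
  if (length(aphv) < min_n)
    sg_error("need at least 10 subjects to classify maturity",
             "sitargrowth_contract_error")
  if (diff(range(aphv)) == 0)
    sg_error("degenerate APHV distribution (all values equal)",
             "sitargrowth_degenerate_error")
  thr <- if (method == "percentile") {
    stats::quantile(aphv, probs = percentiles / 100, type = 7, names = FALSE)
  } else {
    mean(aphv) + c(-1, 1) * stats::sd(aphv)
  }
  label <- ifelse(aphv < thr[1], "early", ifelse(aphv > thr[2], "late", "average"))
  out <- data.frame(
    id = names(aphv) %||% as.character(seq_along(aphv)),
    aphv = unname(aphv), label = label, stringsAsFactors = FALSE
  )
  attr(out, "thresholds") <- thr
  attr(out, "method") <- method
  class(out) <- c("maturity_classification", "data.frame")
  out
}

#' Group summary of landmarks by maturity status
#'
#' Per maturity group and landmark: mean of subject point estimates and a
#' 68% interval from the pooled subject-level posterior draws.  Rows are
#' ordered early/average/late within ATGV, TGV, APHV, PHV.
#'
#' @param classification A [classify_maturity()] result.
#' @param ind_lm An [individual_landmarks()] table covering the same
#'   subjects (its `"draws"` attribute supplies the posterior samples).
#' @return Data frame `measure`, `group`, `mean`, `ci68_low`, `ci68_high`,
#'   `n`; empty groups yield rows of `NA`.
#' @export
group_summary <- function(classification, ind_lm) {
  stopifnot(inherits(classification, "maturity_classification"))
  if (!setequal(classification$id, ind_lm$id))
    sg_error("classification and landmark table cover different subjects",
             "sitargrowth_contract_error")
  dr <- attr(ind_lm, "draws")
  col_of <- match(ind_lm$id, ind_lm$id)  # identity; draws columns follow ind_lm order
  lab <- classification$label[match(ind_lm$id, classification$id)]
  groups <- c("early", "average", "late")
  measures <- c("atgv", "tgv", "aphv", "phv")
  out <- do.call(rbind, lapply(measures, function(m) {
    do.call(rbind, lapply(groups, function(g) {
      cols <- which(lab == g)
      if (length(cols) == 0)
        return(data.frame(measure = m, group = g, mean = NA_real_,
                          ci68_low = NA_real_, ci68_high = NA_real_, n = 0L,
                          stringsAsFactors = FALSE))
      pooled <- as.vector(dr[[m]][, cols, drop = FALSE])
      ci <- ci68(pooled)
      data.frame(measure = m, group = g, mean = mean(ind_lm[[m]][cols]),
                 ci68_low = ci[1], ci68_high = ci[2], n = length(cols),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  # report flag: expected ordering (timing increases, velocity decreases
  # across early -> late)
  flag <- TRUE
  for (m in c("atgv", "aphv")) {
    v <- out$mean[out$measure == m]
    if (!anyNA(v)) flag <- flag && !is.unsorted(v)
  }
  for (m in c("tgv", "phv")) {
    v <- out$mean[out$measure == m]
    if (!anyNA(v)) flag <- flag && !is.unsorted(rev(v))
  }
  attr(out, "ordering_consistent") <- flag
  out
}

#' Timing-tempo correlations
#'
#' Pearson correlations of (ATGV, TGV) and (APHV, PHV) for the full sample
#' and within each maturity group; strata with fewer than 3 subjects get
#' `NA` rather than an error.
#'
#' @param ind_lm An [individual_landmarks()] table.
#' @param classification Optional [classify_maturity()] result for
#'   group-level strata.
#' @return Data frame `stratum`, `pair`, `r`, `n`.
#' @export
timing_tempo_correlations <- function(ind_lm, classification = NULL) {
  strata <- list(full = seq_len(nrow(ind_lm)))
  if (!is.null(classification)) {
    lab <- classification$label[match(ind_lm$id, classification$id)]
    for (g in c("early", "average", "late"))
      strata[[g]] <- which(lab == g)
  }
  pairs <- list(
    atgv_tgv = c("atgv", "tgv"),
    aphv_phv = c("aphv", "phv")
  )
  out <- do.call(rbind, lapply(names(strata), function(s) {
    rows <- strata[[s]]
    do.call(rbind, lapply(names(pairs), function(p) {
      r <- if (length(rows) >= 3) {
        stats::cor(ind_lm[[pairs[[p]][1]]][rows], ind_lm[[pairs[[p]][2]]][rows])
      } else NA_real_
      data.frame(stratum = s, pair = p, r = r, n = length(rows),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Export a maturity classification as CSV
#'
#' @param classification A [classify_maturity()] result.
#' @param sex Sex label for the export.
#' @param path Output path.
#' @export
write_classification_csv <- function(classification, sex, path) {
  thr <- attr(classification, "thresholds")
  out <- data.frame(
    id = classification$id, sex = sex, aphv = classification$aphv,
    label = classification$label,
    threshold_low = thr[1], threshold_high = thr[2],
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
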