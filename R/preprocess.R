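treated_conditions <- function(samples) {
  unique(samples$condition_id[samples$group == "treated"])
}

condition_sample_ids <- function(samples, condition) {
  samples$sample_id[samples$condition_id == condition]
}

# mean intensity per treated condition (averaging replicates)
condition_mean_matrix <- function(intensity, samples) {
  conds <- sort(treated_conditions(samples))
  out <- matrix(vapply(conds, function(cc) {
    cols <- condition_sample_ids(samples, cc)
    rowMeans(intensity[, cols, drop = FALSE])
  }, numeric(nrow(intensity))), nrow = nrow(intensity))
  dimnames(out) <- list(rownames(intensity), conds)
  out
}

#' Non-specific probe filtering
#'
#' Applies the three non-specific filters in order: (1) probes without a
#' gene annotation are removed; (2) probes whose inter-quartile range (IQR)
#' across treated-condition mean intensities falls below the
#' `iqr_quantile` quantile of the probe-IQR distribution are removed;
#' (3) probes for which fewer than `present_frac` of the treated conditions
#' have all replicates flagged present are removed.
#'
#' The quantile is converted to an absolute IQR threshold once, recorded in
#' the report and as an attribute of the returned intensity matrix; when the
#' input matrix already carries such an attribute (the output of a previous
#' pass) the recorded threshold is reused, so the filter is idempotent.
#'
#' @param intensity Probes x samples log2 intensity matrix.
#' @param presence 0/1 matrix of the same shape.
#' @param samples Sample metadata data frame (see [generate_study()]).
#' @param probe2gene Named character vector mapping probe to gene id; probes
#'   absent from it (or mapping to `NA`) count as unannotated.
#' @param iqr_quantile Quantile of the probe-IQR distribution used as the
#'   low-variance cutoff.
#' @param present_frac Minimum fraction of conditions with all replicates
#'   present.
#' @return List with filtered `intensity`, `presence`, `probe2gene`, and a
#'   `report` of counts removed per rule plus the absolute `iqr_threshold`.
#' @export
filter_probes <- function(intensity, presence, samples,
                          probe2gene, iqr_quantile = 0.5,
                          present_frac = 0.25) {
  stopifnot(identical(dim(intensity), dim(presence)))
  probes <- rownames(intensity)

  annotated <- probes %in% names(probe2gene) & !is.na(probe2gene[probes])
  n_no_annot <- sum(!annotated)
  keep <- probes[annotated]
  if (length(keep) == 0L) {
    stop("all probes removed by non-specific filtering")
  }

  cm <- condition_mean_matrix(intensity[keep, , drop = FALSE], samples)
  iqrs <- apply(cm, 1L, function(x) diff(quantile(x, c(0.25, 0.75),
                                                  names = FALSE)))
  thr <- attr(intensity, "iqr_threshold")
  if (is.null(thr)) thr <- unname(quantile(iqrs, iqr_quantile, names = FALSE))
  low_var <- iqrs < thr
  n_low_iqr <- sum(low_var)
  keep <- keep[!low_var]

  conds <- sort(treated_conditions(samples))
  pres_frac <- rowMeans(vapply(conds, function(cc) {
    cols <- condition_sample_ids(samples, cc)
    rowSums(presence[keep, cols, drop = FALSE] == 0L) == 0L
  }, logical(length(keep))))
  absent <- pres_frac < present_frac
  n_absent <- sum(absent)
  keep <- keep[!absent]

  if (length(keep) == 0L) {
    stop("all probes removed by non-specific filtering")
  }
  out_int <- intensity[keep, , drop = FALSE]
  attr(out_int, "iqr_threshold") <- thr
  list(intensity = out_int,
       presence = presence[keep, , drop = FALSE],
       probe2gene = probe2gene[keep],
       report = list(n_input = length(probes),
                     n_no_annotation = n_no_annot,
                     n_low_iqr = n_low_iqr,
                     n_absent = n_absent,
                     n_kept = length(keep),
                     iqr_threshold = thr))
}

#' Per-condition log-ratios against matched controls
#'
#' For every treated condition, the mean log2 intensity over its replicates
#' minus the mean over the replicates of its matched control condition.
#'
#' @param intensity Probes/genes x samples log2 intensity matrix.
#' @param samples Sample metadata data frame.
#' @return Matrix with one column per treated condition.
#' @export
condition_log_ratios <- function(intensity, samples) {
  conds <- sort(treated_conditions(samples))
  out <- matrix(vapply(conds, function(cc) {
    rows <- samples[samples$condition_id == cc, , drop = FALSE]
    ctrl <- unique(rows$control_condition_id)
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) != 1L ||
        !any(samples$condition_id == ctrl)) {
      stop("condition '", cc, "' has no resolvable control condition")
    }
    t_cols <- rows$sample_id
    c_cols <- condition_sample_ids(samples, ctrl)
    rowMeans(intensity[, t_cols, drop = FALSE]) -
      rowMeans(intensity[, c_cols, drop = FALSE])
  }, numeric(nrow(intensity))), nrow = nrow(intensity))
  dimnames(out) <- list(rownames(intensity), conds)
  out
}

#' Collapse probe-level rows to gene level
#'
#' When several probes map to one gene, the probe with the highest IQR
#' across conditions is retained; ties break to the lexicographically
#' smallest probe identifier.
#'
#' @param mat Probe-level matrix (probes x conditions).
#' @param probe2gene Named character vector covering all rows of `mat`.
#' @return Gene-level matrix; attribute `"kept_probes"` records the probe
#'   retained for each gene.
#' @export
collapse_probes <- function(mat, probe2gene) {
  probes <- rownames(mat)
  if (!all(probes %in% names(probe2gene))) {
    stop("probe2gene does not cover all retained probes")
  }
  genes <- probe2gene[probes]
  iqrs <- apply(mat, 1L, function(x) diff(quantile(x, c(0.25, 0.75),
                                                   names = FALSE)))
  ord <- order(genes, -iqrs, probes)
  first <- !duplicated(genes[ord])
  kept <- probes[ord][first]
  out <- mat[kept, , drop = FALSE]
  rownames(out) <- genes[kept]
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "kept_probes") <- setNames(kept[order(genes[kept])],
                                       sort(unname(genes[kept])))
  out
}

#' Select disease-producing conditions by histopathology severity
#'
#' Returns treated conditions whose histopathology severity score is
#' strictly greater than `score_threshold`, sorted.
#'
#' @param samples Sample metadata data frame.
#' @param score_threshold Integer severity threshold (strict inequality).
#' @return Sorted character vector of condition identifiers (possibly
#'   empty, with a warning).
#' @export
select_disease_conditions <- function(samples, score_threshold = 1L) {
  tr <- samples[samples$group == "treated", , drop = FALSE]
  scores <- tapply(tr$histopath_score, tr$condition_id,
                   function(x) max(x, na.rm = TRUE))
  sel <- names(scores)[!is.na(scores) & scores > score_threshold]
  if (length(sel) == 0L) {
    warning("no condition exceeds histopathology score ", score_threshold)
  }
  sort(sel)
}

#' Replicate-clustering quality control of candidate conditions
#'
#' Hierarchically clusters the treated replicates of the candidate
#' conditions together with their control replicates (distance
#' 1 - Pearson correlation of gene-centred intensity profiles, average
#' linkage), cuts the dendrogram into two groups, and fails any condition
#' whose treated replicates all fall into the group dominated by control
#' samples — the signature of a treatment indistinguishable from its
#' controls.
#'
#' @param intensity Genes x samples log2 intensity matrix.
#' @param samples Sample metadata data frame.
#' @param candidate_conditions Character vector of treated condition ids.
#' @return Data frame with one row per candidate condition (`condition_id`,
#'   `n_treated`, `n_with_controls`, `pass`).
#' @export
qc_replicate_clustering <- function(intensity, samples,
                                    candidate_conditions) {
  if (length(candidate_conditions) < 2L) {
    stop("replicate-clustering QC needs at least 2 candidate conditions")
  }
  tr <- samples[samples$condition_id %in% candidate_conditions &
                  samples$group == "treated", , drop = FALSE]
  ctrl_ids <- unique(tr$control_condition_id)
  ct <- samples[samples$condition_id %in% ctrl_ids, , drop = FALSE]
  cols <- c(tr$sample_id, ct$sample_id)
  if (length(cols) < 2L) stop("fewer than 2 samples for QC clustering")
  x <- intensity[, cols, drop = FALSE]
  x <- x - rowMeans(x)  # centre genes so treatment structure drives r
  d <- stats::as.dist(1 - cor(x))
  cl <- cutree(hclust(d, method = "average"), k = 2L)
  is_ctrl <- cols %in% ct$sample_id
  ctrl_frac <- c(mean(cl[is_ctrl] == 1L), mean(cl[is_ctrl] == 2L))
  ctrl_group <- which.max(ctrl_frac)
  res <- do.call(rbind, lapply(sort(unique(tr$condition_id)), function(cc) {
    reps <- tr$sample_id[tr$condition_id == cc]
    in_ctrl <- sum(cl[reps] == ctrl_group)
    data.frame(condition_id = cc, n_treated = length(reps),
               n_with_controls = in_ctrl,
               pass = in_ctrl < length(reps),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
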