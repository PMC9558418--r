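#' Tumor-versus-all-normal-tissues overexpression screen
#'
#' Surface-target discovery for antibody-directed delivery asks for genes
#' that are overexpressed in the tumor entity compared to \emph{every}
#' normal tissue type (the screen that yielded 36 candidates, and among them
#' the surface proteins GPR64, FAT4 and LECT1, from 50 Ewing-sarcoma and 928
#' normal-tissue microarrays spanning 70 tissue types). One one-sided test is
#' run per gene per tissue; Benjamini-Hochberg correction is applied across
#' the whole gene x tissue family; a single failing tissue vetoes the call.
#'
#' @name target-screen
NULL

#' Screen parameters
#'
#' @param test \code{"welch_t"} (default; one-sided Welch t on log2
#'   intensities) or \code{"mann_whitney"}.
#' @param alpha FDR level, in (0, 1).
#' @param min_delta minimal tumor-minus-tissue mean difference in log2 units,
#'   applied against the \emph{highest} normal tissue (default 1 = 2-fold).
#' @param min_tissue_n tissues with fewer samples are excluded with a warning
#'   (default 3).
#' @param tumor_label group label identifying tumor samples.
#' @export
screen_params <- function(test = c("welch_t", "mann_whitney"), alpha = 0.05,
                          min_delta = 1, min_tissue_n = 3L,
                          tumor_label = "tumor") {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1, min_delta >= 0)
  structure(list(test = test, alpha = alpha, min_delta = min_delta,
                 min_tissue_n = as.integer(min_tissue_n),
                 tumor_label = tumor_label),
            class = "screen_params")
}

#' Screen for genes overexpressed versus every normal tissue
#'
#' @param matrix numeric matrix, genes x samples, log2 intensities; rownames
#'   are gene ids (must be unique), colnames sample ids.
#' @param labels named character vector sample -> group; the tumor group is
#'   \code{params$tumor_label}, every other value is a normal tissue type.
#' @param params a \code{\link{screen_params}}.
#' @return data.frame (one row per tested gene): \code{gene_id},
#'   \code{tumor_mean}, \code{max_normal_mean}, \code{max_normal_tissue},
#'   \code{delta_vs_max}, \code{max_padj} (largest BH-adjusted p across
#'   tissues), \code{called}. Matrices of raw and adjusted p-values
#'   (genes x tissues) are attached as attributes \code{p} and \code{padj}.
#'   A gene is called only if, for every tissue, the adjusted one-sided p is
#'   below alpha and the tumor mean exceeds the tissue mean, and additionally
#'   the tumor mean beats the highest tissue mean by \code{min_delta}.
#'   All-constant gene rows are untestable and dropped with a warning.
#' @export
screen_overexpressed <- function(matrix, labels, params = screen_params()) {
  stopifnot(inherits(params, "screen_params"), is.matrix(matrix))
  if (anyDuplicated(rownames(matrix))) stop("duplicate gene ids")
  if (is.null(names(labels)) || !all(colnames(matrix) %in% names(labels))) {
    stop("every sample column must be labelled")
  }
  labels <- labels[colnames(matrix)]
  is_tumor <- labels == params$tumor_label
  if (!any(is_tumor)) stop("no samples labelled '", params$tumor_label, "'")
  tissues <- sort(unique(labels[!is_tumor]))
  if (length(tissues) < 2L) stop("need at least 2 normal tissue types")
  sizes <- table(labels[!is_tumor])
  small <- names(sizes)[sizes < params$min_tissue_n]
  if (length(small)) {
    warning("excluding tissue(s) with n < ", params$min_tissue_n, ": ",
            paste(small, collapse = ", "))
    tissues <- setdiff(tissues, small)
    if (length(tissues) < 2L) stop("fewer than 2 testable tissues remain")
  }

  constant <- apply(matrix, 1L, function(r) length(unique(r)) == 1L)
  if (any(constant)) {
    warning("skipping ", sum(constant), " all-constant gene row(s)")
    matrix <- matrix[!constant, , drop = FALSE]
  }
  genes <- rownames(matrix)
  tum <- matrix[, is_tumor, drop = FALSE]
  n1 <- ncol(tum)
  m1 <- rowMeans(tum)
  v1 <- rowSums((tum - m1)^2) / (n1 - 1L)

  p <- matrix(NA_real_, nrow = length(genes), ncol = length(tissues),
              dimnames = list(genes, tissues))
  tissue_means <- p
  for (tis in tissues) {
    grp <- matrix[, labels == tis, drop = FALSE]
    n2 <- ncol(grp)
    m2 <- rowMeans(grp)
    tissue_means[, tis] <- m2
    if (params$test == "welch_t") {
      v2 <- rowSums((grp - m2)^2) / (n2 - 1L)
      se2 <- v1 / n1 + v2 / n2
      tstat <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
      pv <- pt(tstat, df, lower.tail = FALSE)
      ## zero pooled variance: direction decides
      degenerate <- se2 == 0
      pv[degenerate] <- ifelse(m1[degenerate] > m2[degenerate], 0, 1)
      p[, tis] <- pv
    } else {
      p[, tis] <- vapply(seq_along(genes), function(i) {
        stats::wilcox.test(tum[i, ], grp[i, ], alternative = "greater",
                           exact = FALSE, correct = TRUE)$p.value
      }, numeric(1))
    }
  }
  padj <- matrix(stats::p.adjust(p, method = "BH"), nrow = nrow(p),
                 dimnames = dimnames(p))
  greater <- tum_greater_all <- rowSums(m1 > tissue_means) == length(tissues)
  max_idx <- max.col(tissue_means, ties.method = "first")
  max_normal_mean <- tissue_means[cbind(seq_along(genes), max_idx)]
  delta <- m1 - max_normal_mean
  max_padj <- apply(padj, 1L, max)
  called <- (max_padj < params$alpha) & greater & (delta >= params$min_delta)
  res <- data.frame(gene_id = genes, tumor_mean = m1,
                    max_normal_mean = max_normal_mean,
                    max_normal_tissue = tissues[max_idx],
                    delta_vs_max = delta, max_padj = max_padj,
                    called = called, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "p") <- p
  attr(res, "padj") <- padj
  res
}

#' Filter screen calls to surface-protein candidates
#'
#' @param results output of \code{\link{screen_overexpressed}}.
#' @param surface_list character vector of surface-protein gene ids, or a
#'   named logical vector gene -> flag; genes absent from the list are
#'   treated as not surface.
#' @return the called-and-surface subset, ranked by \code{delta_vs_max}
#'   descending.
#' @export
filter_surface <- function(results, surface_list) {
  surface_ids <- if (is.logical(surface_list)) {
    names(surface_list)[surface_list]
  } else as.character(surface_list)
  cand <- results[results$called & results$gene_id %in% surface_ids, ,
                  drop = FALSE]
  cand <- cand[order(-cand$delta_vs_max, cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
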