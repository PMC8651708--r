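#' Recode allele dosages to the centered unit scale
#'
#' Maps a dosage `d` in `{0, ..., q}` to `(d - q/2) / (q/2)`, so tetraploid
#' dosages `{0, 1, 2, 3, 4}` become `{-1, -0.5, 0, 0.5, 1}`. Missing entries
#' are imputed to the marker mean of the recoded matrix, which keeps the
#' relationship matrix built from it positive semidefinite (distance
#' measures, by contrast, use pairwise deletion and never see this
#' imputation).
#'
#' @param panel a [dosage_panel].
#' @return numeric matrix `W`, individuals x markers.
#' @export
recode_dosage <- function(panel) {
  validate_panel(panel)
  q <- panel$ploidy
  W <- (panel$dosages - q / 2) / (q / 2)
  if (anyNA(W)) {
    mu <- colMeans(W, na.rm = TRUE)
    idx <- which(is.na(W))
    W[idx] <- mu[(idx - 1) %/% nrow(W) + 1]
  }
  W
}

#' VanRaden additive genomic relationship matrix for dosage data
#'
#' With `W` the recoded marker matrix ([recode_dosage]) and `p_j` the
#' allele frequency of marker j on the counted (alternate) allele,
#' `mean(dosage_j)/q`, the centered matrix is `Q_ij = W_ij + 1 - 2 p_j` and
#' `A = Q Q' / (2 * sum_j p_j (1 - p_j))`. Taking `p_j` on the counted
#' allele is what makes `1 - 2 p_j` exactly center `W` (each column of `Q`
#' has mean zero when `p_j` is estimated from the panel itself, so
#' `A %*% 1 = 0`); the denominator is symmetric in `p_j` vs `1 - p_j`.
#'
#' @param panel a [dosage_panel] with at least two polymorphic markers.
#' @return a `relationship_matrix`: list with `A` (symmetric PSD matrix with
#'   ids), `p` (reference-allele frequencies) and `denom`.
#' @export
vanraden_A <- function(panel) {
  validate_panel(panel)
  q <- panel$ploidy
  W <- recode_dosage(panel)
  p <- colMeans(panel$dosages, na.rm = TRUE) / q
  denom <- 2 * sum(p * (1 - p))
  poly <- apply(panel$dosages, 2, function(x) {
    length(unique(x[!is.na(x)])) > 1
  })
  if (sum(poly) < 2 || denom <= .Machine$double.eps) {
    stop("fewer than two polymorphic markers: VanRaden denominator degenerate")
  }
  Q <- sweep(W, 2, 2 * p - 1, "-")
  A <- tcrossprod(Q) / denom
  A <- (A + t(A)) / 2
  structure(list(A = A, p = p, denom = denom, ids = rownames(A)),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix: %d individuals, mean diag %.3f\n",
              nrow(x$A), mean(diag(x$A))))
  invisible(x)
}
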