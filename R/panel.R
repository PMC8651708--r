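#' Construct a dosage panel
#'
#' A dosage panel holds biallelic SNP genotypes for a set of individuals as
#' counts of the alternate allele, so for a tetraploid the genotype classes
#' AAAA, AAAB, AABB, ABBB, BBBB are coded 0, 1, 2, 3, 4. Missing calls are
#' stored as `NA` and never imputed at this level; downstream computations
#' document their own handling of missing entries.
#'
#' @param dosages integer matrix, individuals in rows and markers in columns.
#'   Row names (or `ids`) give individual identifiers, column names (or the
#'   `map`) give marker identifiers.
#' @param ploidy even integer, number of chromosome copies (default 4).
#' @param map optional data.frame with columns `marker`, `chrom`, `pos`
#'   (1-based). `chrom` equal to `"0"`, `""` or `NA` marks an unmapped marker.
#' @param strata optional character/factor vector of per-individual stratum
#'   labels (e.g. market-class groups), named by or ordered as the rows.
#' @param ids optional character vector of individual ids overriding row names.
#' @return An object of class `dosage_panel`: a list with elements `dosages`,
#'   `ploidy`, `map`, `strata`.
#' @export
dosage_panel <- function(dosages, ploidy = 4, map = NULL, strata = NULL,
                         ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!is.null(ids)) rownames(dosages) <- ids
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- if (!is.null(map)) as.character(map$marker) else
      paste0("snp", seq_len(ncol(dosages)))
  }
  if (is.null(map)) {
    map <- data.frame(marker = colnames(dosages), chrom = "0",
                      pos = NA_integer_, stringsAsFactors = FALSE)
  }
  map$marker <- as.character(map$marker)
  if (!is.null(strata)) {
    if (!is.null(names(strata))) strata <- strata[rownames(dosages)]
    strata <- as.character(strata)
    names(strata) <- rownames(dosages)
  }
  obj <- structure(list(dosages = dosages, ploidy = as.integer(ploidy),
                        map = map, strata = strata),
                   class = "dosage_panel")
  validate_panel(obj)
  obj
}

validate_panel <- function(panel) {
  stopifnot(inherits(panel, "dosage_panel"))
  d <- panel$dosages
  q <- panel$ploidy
  if (q < 2 || q %% 2 != 0) stop("ploidy must be an even integer >= 2")
  ids <- rownames(d)
  if (anyDuplicated(ids)) {
    stop("duplicate genotype ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mk <- colnames(d)
  if (anyDuplicated(mk)) {
    stop("duplicate marker ids: ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "))
  }
  if (nrow(panel$map) != ncol(d) || !identical(panel$map$marker, mk)) {
    stop("marker map does not match dosage columns")
  }
  v <- d[!is.na(d)]
  if (length(v) && (any(v < 0) || any(v > q) || any(v != round(v)))) {
    bad <- which(!is.na(d) & (d < 0 | d > q | d != round(d)), arr.ind = TRUE)[1, ]
    stop(sprintf("dosage out of range or non-integer at individual '%s', marker '%s'",
                 ids[bad[1]], mk[bad[2]]))
  }
  if (!is.null(panel$strata) && length(panel$strata) != nrow(d)) {
    stop("strata length does not match number of individuals")
  }
  invisible(panel)
}

#' @export
print.dosage_panel <- function(x, ...) {
  d <- x$dosages
  cat(sprintf("dosage_panel: %d individuals x %d markers (ploidy %d)\n",
              nrow(d), ncol(d), x$ploidy))
  miss <- mean(is.na(d))
  cat(sprintf("  missing: %.2f%%", 100 * miss))
  if (!is.null(x$strata)) {
    tb <- table(x$strata)
    cat("  strata: ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.dosage_panel <- function(x) dim(x$dosages)

panel_ids <- function(panel) rownames(panel$dosages)

# restrict a panel to a subset of marker columns (logical or index)
subset_markers <- function(panel, keep) {
  panel$dosages <- panel$dosages[, keep, drop = FALSE]
  panel$map <- panel$map[keep, , drop = FALSE]
  rownames(panel$map) <- NULL
  validate_panel(panel)
  panel
}

#' Read a dosage panel from disk
#'
#' Two dialects are supported. `tsv`: individuals as rows, first column the
#' genotype id, remaining columns integer dosages (header row carries marker
#' ids; `NA` marks missing calls). `vcf`: a VCF 4.x file where dosages are
#' taken from the per-sample `DS` field (rounded to integer) or, if no `DS` is
#' present, by counting alternate alleles in a tetraploid `GT`; files mixing
#' the two sources are rejected.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param ploidy panel ploidy, default 4.
#' @param map optional marker map data.frame (tsv only; the VCF reader builds
#'   the map from CHROM/POS).
#' @param strata optional per-individual stratum labels.
#' @return a [dosage_panel].
#' @export
read_dosage_panel <- function(path, format = c("tsv", "vcf"), ploidy = 4,
                              map = NULL, strata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character")
    ids <- tab[[1]]
    raw <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                   dimnames = dimnames(raw)))
    bad <- which(!is.na(raw) & raw != "NA" & is.na(num), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric dosage '%s' at row %d (id '%s'), column '%s'",
                   raw[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                   colnames(raw)[bad[1, 2]]))
    }
    oob <- which(!is.na(num) & (num < 0 | num > ploidy | num != round(num)),
                 arr.ind = TRUE)
    if (nrow(oob)) {
      stop(sprintf("dosage %s out of range [0,%d] at id '%s', marker '%s'",
                   format(num[oob[1, 1], oob[1, 2]]), ploidy, ids[oob[1, 1]],
                   colnames(num)[oob[1, 2]]))
    }
    rownames(num) <- ids
    dosage_panel(num, ploidy = ploidy, map = map, strata = strata)
  } else {
    read_vcf_dosage(path, ploidy = ploidy, strata = strata)
  }
}

read_vcf_dosage <- function(path, ploidy = 4, strata = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt_keys <- unique(unlist(lapply(strsplit(v@gt[, "FORMAT"], ":"), identity)))
  has_ds <- "DS" %in% fmt_keys
  has_gt <- "GT" %in% fmt_keys
  per_row_ds <- grepl("(^|:)DS(:|$)", v@gt[, "FORMAT"])
  if (has_ds && !all(per_row_ds)) {
    stop("mixed dosage sources in VCF: some records carry DS, others do not")
  }
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- round(ds)
  } else if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(s) {
      if (is.na(s)) return(NA_real_)
      a <- strsplit(s, "[/|]")[[1]]
      if (any(a == ".")) return(NA_real_)
      sum(a != "0")
    }
    dos <- matrix(vapply(gt, count_alt, numeric(1)), nrow = nrow(gt),
                  dimnames = dimnames(gt))
  } else {
    stop("VCF has neither DS nor GT fields")
  }
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- paste0("snp", which(is.na(ids)))
  map <- data.frame(marker = ids, chrom = vcfR::getCHROM(v),
                    pos = vcfR::getPOS(v), stringsAsFactors = FALSE)
  dosages <- t(dos)
  colnames(dosages) <- ids
  dosage_panel(dosages, ploidy = ploidy, map = map, strata = strata)
}

#' Write a dosage panel as a tab-delimited file
#'
#' Inverse of [read_dosage_panel] for the tsv dialect: first column `id`,
#' then one integer column per marker. Round-trips dosages exactly.
#'
#' @param panel a [dosage_panel].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_panel <- function(panel, path) {
  validate_panel(panel)
  out <- data.frame(id = panel_ids(panel), panel$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker quality control for a dosage panel
#'
#' Removes, in this order of attribution: monomorphic markers, unmapped
#' markers, markers with minor allele frequency strictly below `maf_min`, and
#' markers missing in strictly more than `max_missing_individuals`
#' individuals. Allele frequency at marker j is `mean(dosage_j)/ploidy` over
#' non-missing individuals. Markers exactly at the MAF threshold, or missing
#' in exactly `max_missing_individuals` individuals, are retained.
#'
#' @param panel a [dosage_panel].
#' @param maf_min minor-allele-frequency threshold (default 0.05; strict `<`).
#' @param max_missing_individuals absolute missing-call count above which a
#'   marker is dropped (default 30, tied to a 190-line panel). Set
#'   `max_missing_frac` instead to use a fraction of the panel size.
#' @param max_missing_frac optional fraction overriding
#'   `max_missing_individuals`.
#' @param drop_unmapped drop markers with chrom "0"/""/NA (default TRUE).
#' @param drop_monomorphic drop markers with a single observed dosage class
#'   (default TRUE).
#' @return list with elements `panel` (filtered) and `report` (a `qc_report`
#'   with first-failure counts per filter, the union count, and thresholds).
#' @export
qc_filter <- function(panel, maf_min = 0.05, max_missing_individuals = 30,
                      max_missing_frac = NULL, drop_unmapped = TRUE,
                      drop_monomorphic = TRUE) {
  validate_panel(panel)
  d <- panel$dosages
  q <- panel$ploidy
  n <- nrow(d)
  if (!is.null(max_missing_frac)) {
    max_missing_individuals <- max_missing_frac * n
  }
  n_miss <- colSums(is.na(d))
  n_obs <- n - n_miss
  mono <- apply(d, 2, function(x) length(unique(x[!is.na(x)])) <= 1)
  unmapped <- if (drop_unmapped) {
    ch <- panel$map$chrom
    is.na(ch) | ch == "0" | ch == ""
  } else rep(FALSE, ncol(d))
  freq <- colMeans(d, na.rm = TRUE) / q
  maf <- pmin(freq, 1 - freq)
  low_maf <- !is.na(maf) & maf < maf_min
  high_miss <- n_miss > max_missing_individuals
  if (!drop_monomorphic) mono <- rep(FALSE, ncol(d))

  # first-failure attribution in the order the filters are described
  fail <- cbind(mono, unmapped, low_maf, high_miss)
  first <- apply(fail, 1, function(z) if (any(z)) which(z)[1] else 0L)
  keep <- first == 0L
  if (!any(keep)) stop("QC removed every marker: empty panel")
  report <- structure(list(
    n_input = ncol(d),
    n_monomorphic = sum(first == 1L),
    n_unmapped = sum(first == 2L),
    n_low_maf = sum(first == 3L),
    n_high_missing = sum(first == 4L),
    n_any = colSums(fail), # per-filter totals ignoring attribution order
    n_removed_union = sum(!keep),
    n_retained = sum(keep),
    thresholds = list(maf_min = maf_min,
                      max_missing_individuals = max_missing_individuals,
                      drop_unmapped = drop_unmapped,
                      drop_monomorphic = drop_monomorphic)
  ), class = "qc_report")
  list(panel = subset_markers(panel, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("marker QC report\n")
  cat(sprintf("  input markers:    %d\n", x$n_input))
  cat(sprintf("  monomorphic:      %d\n", x$n_monomorphic))
  cat(sprintf("  unmapped:         %d\n", x$n_unmapped))
  cat(sprintf("  MAF < %.3g:       %d\n", x$thresholds$maf_min, x$n_low_maf))
  cat(sprintf("  missing > %g:     %d\n",
              x$thresholds$max_missing_individuals, x$n_high_missing))
  cat(sprintf("  retained:         %d (removed %d)\n",
              x$n_retained, x$n_removed_union))
  invisible(x)
}
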