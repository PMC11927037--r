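#' @title GWAS / eQTL summary statistics containers and TSV I/O
#' @name sumstats-io
#' @description
#' A `sumstats` object holds one trait's per-variant association estimates:
#' SNP identifier, chromosome, 1-based position, effect and other allele,
#' effect-allele frequency (optionally missing), effect size (log-odds or SD
#' units), its standard error, p-value, and sample size.  Rows violating the
#' container invariants (`se > 0`, `p` in (0, 1], distinct A/C/G/T alleles,
#' frequency in [0, 1], unique SNP ids) are dropped at construction and
#' counted in a QC tally rather than raising an error, mirroring how GWAS
#' pipelines quarantine malformed rows.
NULL

# canonical external column names (internal = external)
SUMSTAT_COLS <- c(
  snp_id = "snp", chrom = "chr", pos = "pos",
  effect_allele = "ea", other_allele = "oa", eaf = "eaf",
  beta = "beta", se = "se", pvalue = "p", n = "n"
)

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics object
#'
#' @param trait_id character scalar naming the trait (e.g. a gene id).
#' @param trait_type one of `"eqtl_gene"`, `"mediator"`, `"outcome"`.
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @param gene_symbol HGNC-style symbol for eQTL traits; may be `""`
#'   (symbol-less genes are filtered by [smr_screen()]).
#' @param validate drop invalid rows and record a QC tally (default `TRUE`).
#' @return object of class `sumstats`: a list with elements `trait_id`,
#'   `trait_type`, `gene_symbol`, `records` (validated data.frame) and `qc`
#'   (named integer tally of dropped rows).
#' @export
sumstats <- function(trait_id, trait_type = c("eqtl_gene", "mediator", "outcome"),
                     records, gene_symbol = "", validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  need <- setdiff(names(SUMSTAT_COLS), "eaf")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop_mrtriage(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      "mrtriage_format_error"
    )
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  records <- records[names(SUMSTAT_COLS)]
  qc <- integer(0)
  if (validate) {
    v <- validate_variants(records)
    records <- v$records
    qc <- v$tally
  }
  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         gene_symbol = gene_symbol, records = records, qc = qc),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s%s): %d variants",
              x$trait_id, x$trait_type,
              if (nzchar(x$gene_symbol)) paste0(", symbol ", x$gene_symbol) else "",
              nrow(x$records)))
  if (sum(x$qc) > 0) {
    cat(sprintf(", %d dropped at QC [%s]", sum(x$qc),
                paste(sprintf("%s: %d", names(x$qc)[x$qc > 0], x$qc[x$qc > 0]),
                      collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# Row-level invariant enforcement.  Returns the kept rows plus a named tally
# of drops; checks are applied in a fixed order so each bad row is counted
# exactly once.
validate_variants <- function(df) {
  tally <- c(bad_allele = 0L, bad_se = 0L, bad_p = 0L, bad_pos = 0L,
             bad_n = 0L, bad_eaf = 0L, dup = 0L)
  bad <- rep(FALSE, nrow(df))
  flag <- function(cond, what) {
    cond[is.na(cond)] <- TRUE
    new <- cond & !bad
    tally[what] <<- tally[what] + sum(new)
    bad <<- bad | cond
  }
  ea <- toupper(df$effect_allele); oa <- toupper(df$other_allele)
  flag(!(ea %in% VALID_ALLELES) | !(oa %in% VALID_ALLELES) | ea == oa, "bad_allele")
  flag(!is.finite(df$se) | df$se <= 0, "bad_se")
  flag(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1, "bad_p")
  flag(!is.finite(df$pos) | df$pos < 1, "bad_pos")
  flag(!is.finite(df$n) | df$n <= 0, "bad_n")
  eaf_bad <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  flag(eaf_bad, "bad_eaf")
  dup <- duplicated(df$snp_id) & !bad
  tally["dup"] <- sum(dup)
  bad <- bad | dup
  df$effect_allele <- ea
  df$other_allele <- oa
  # canonical storage types so in-memory and TSV-parsed containers agree
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$eaf <- as.numeric(df$eaf)
  df$n <- as.numeric(df$n)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, tally = tally)
}

#' Read summary statistics from a tab-separated file
#'
#' Expects a header with columns `snp chr pos ea oa eaf beta se p n`
#' (override the mapping with `column_map`, a named character vector from
#' internal names such as `snp_id` to the file's column names).  The `eaf`
#' column is optional; all others are mandatory.
#'
#' @inheritParams sumstats
#' @param path TSV file path.
#' @param column_map named character vector overriding the default columns.
#' @return a validated [sumstats()] object; dropped rows are tallied in `$qc`.
#' @export
read_sumstats <- function(path, trait_id, trait_type = "eqtl_gene",
                          column_map = NULL, gene_symbol = "") {
  if (!file.exists(path)) {
    stop_mrtriage(paste0("file not found: ", path), "mrtriage_format_error")
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    stop_mrtriage(paste0("empty summary-statistics file: ", path),
                  "mrtriage_empty_input")
  }
  cmap <- SUMSTAT_COLS
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  present <- cmap %in% names(raw)
  mandatory <- names(cmap) != "eaf"
  if (any(!present & mandatory)) {
    stop_mrtriage(
      paste0("missing mandatory column(s): ",
             paste(cmap[!present & mandatory], collapse = ", ")),
      "mrtriage_format_error"
    )
  }
  cols <- lapply(names(cmap), function(internal) {
    if (present[match(internal, names(cmap))]) raw[[cmap[[internal]]]]
    else rep(NA_real_, nrow(raw))
  })
  records <- as.data.frame(stats::setNames(cols, names(cmap)),
                           stringsAsFactors = FALSE)
  sumstats(trait_id, trait_type, records, gene_symbol = gene_symbol)
}

#' Write summary statistics to a tab-separated file
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_sumstats(write_sumstats(x))` round-trips every field exactly.
#'
#' @param ss a [sumstats()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "sumstats"))
  out <- ss$records
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("pos", "n"))
  for (j in which(num)) {
    out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
  }
  names(out) <- SUMSTAT_COLS[names(out)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Linkage-disequilibrium correlation matrix
#'
#' @param r square numeric matrix of pairwise allelic correlations (r, not
#'   r-squared); must be symmetric with unit diagonal and entries in
#'   \[-1, 1\].
#' @param snp_ids SNP identifiers in matrix order (defaults to `rownames(r)`).
#' @return object of class `ld_matrix` with elements `snp_ids` and `r`.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(snp_ids)) stop_mrtriage("LD matrix needs SNP ids", "mrtriage_format_error")
  if (nrow(r) != ncol(r) || nrow(r) != length(snp_ids)) {
    stop_mrtriage("LD matrix must be square with one id per row", "mrtriage_format_error")
  }
  if (max(abs(r - t(r))) > 1e-8) {
    stop_mrtriage("LD matrix must be symmetric", "mrtriage_format_error")
  }
  if (max(abs(diag(r) - 1)) > 1e-8 || max(abs(r)) > 1 + 1e-8) {
    stop_mrtriage("LD matrix must have unit diagonal and |r| <= 1",
                  "mrtriage_format_error")
  }
  r <- (r + t(r)) / 2
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r = r), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d SNPs\n", length(x$snp_ids)))
  invisible(x)
}

#' Read / write an LD matrix as TSV (header row and column of SNP ids)
#' @param path TSV path.
#' @return [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  ld_matrix(m, snp_ids = rownames(m))
}

#' @rdname read_ld_matrix
#' @param ld an [ld_matrix()] object.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- as.data.frame(ld$r)
  out <- cbind(snp = ld$snp_ids, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# subset an ld_matrix to a set of SNPs (error if any are missing)
ld_subset <- function(ld, snps) {
  miss <- setdiff(snps, ld$snp_ids)
  if (length(miss) > 0L) {
    stop_mrtriage(
      paste0("LD matrix does not cover SNP(s): ", paste(miss, collapse = ", ")),
      "mrtriage_ld_coverage_error"
    )
  }
  ld_matrix(ld$r[snps, snps, drop = FALSE], snp_ids = snps)
}
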