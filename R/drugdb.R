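#' @title Cross-database druggability annotation and direction triage
#' @name drugdb
#' @description
#' A candidate gene from the mediation screen is considered adequately
#' validated as a drug target when drugs against it are recorded in all
#' three reference catalogues (DrugBank-, ChEMBL- and DGIdb-style tables).
#' Validation alone is not enough for repurposing: the drug's mechanism must
#' act against the gene's causal direction.  A gene whose expression
#' *raises* risk needs an inhibitor; a gene whose expression *lowers* risk
#' needs an agonist.  Modulators, cofactors and unknown mechanisms are never
#' counted as compatible.
NULL

DRUG_DATABASES <- c("drugbank", "chembl", "dgidb")

MECHANISM_MAP <- c(
  inhibitor = "inhibitor", antagonist = "inhibitor", blocker = "inhibitor",
  agonist = "agonist", activator = "agonist",
  modulator = "modulator", cofactor = "cofactor", unknown = "unknown"
)

#' Normalize drug-mechanism strings to the closed vocabulary
#'
#' Case-insensitive mapping onto `inhibitor`, `agonist`, `modulator`,
#' `cofactor`, `unknown` (with pharmacological synonyms such as "antagonist"
#' folded into `inhibitor`).  Unrecognized strings map to `unknown` with a
#' warning.
#'
#' @param x character vector of mechanism strings.
#' @return character vector over the closed vocabulary.
#' @export
normalize_mechanism <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key[is.na(key) | key == ""] <- "unknown"
  out <- unname(MECHANISM_MAP[key])
  bad <- is.na(out)
  if (any(bad)) {
    warning("unrecognized drug mechanism(s) mapped to 'unknown': ",
            paste(unique(x[bad]), collapse = ", "))
    out[bad] <- "unknown"
  }
  out
}

#' Read a drug-target record table
#'
#' TSV with columns `target`, `database`, `accession_id`, `formula`,
#' `mechanism`.  Mechanisms are normalized with [normalize_mechanism()];
#' the database name must belong to the closed set
#' `drugbank` / `chembl` / `dgidb`.
#'
#' @param path TSV path.
#' @param database expected database name (checked against the file when
#'   given).
#' @return validated data.frame of drug-target records.
#' @export
read_drug_table <- function(path, database = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target", "database", "accession_id", "formula", "mechanism")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop_mrtriage(paste0("drug table missing column(s): ",
                         paste(miss, collapse = ", ")),
                  "mrtriage_format_error")
  }
  df$database <- tolower(df$database)
  if (!all(df$database %in% DRUG_DATABASES)) {
    stop_mrtriage(paste0("unknown database name(s): ",
                         paste(setdiff(unique(df$database), DRUG_DATABASES),
                               collapse = ", ")),
                  "mrtriage_format_error")
  }
  if (!is.null(database) && !all(df$database == database)) {
    stop_mrtriage(sprintf("expected records from '%s'", database),
                  "mrtriage_format_error")
  }
  df$mechanism <- normalize_mechanism(df$mechanism)
  df
}

#' Annotate screened genes with cross-database drug evidence
#'
#' A gene is `validated` if and only if it has at least one record in each
#' of the three databases; matching on gene symbol is case-insensitive.
#'
#' @param genes data.frame with columns `gene` (symbol) and
#'   `causal_direction` (`"positive"` / `"negative"`, e.g. the sign of the
#'   mediated effect).
#' @param records one combined data.frame of drug-target records (or a list
#'   of per-database data.frames, which are row-bound).
#' @return `druggability_calls` data.frame: per gene the database hits,
#'   `validated`, and placeholders for the direction verdict filled by
#'   [direction_compatibility()].
#' @export
annotate_targets <- function(genes, records) {
  stopifnot(all(c("gene", "causal_direction") %in% names(genes)))
  stopifnot(all(genes$causal_direction %in% c("positive", "negative")))
  if (is.data.frame(records)) records <- list(records)
  rec <- do.call(rbind, lapply(records, function(r) {
    r$mechanism <- normalize_mechanism(r$mechanism)
    r
  }))
  rec$target_key <- toupper(rec$target)
  hits <- function(gene, db) sum(rec$target_key == toupper(gene) & rec$database == db)
  out <- genes
  for (db in DRUG_DATABASES) {
    out[[paste0("n_", db)]] <- vapply(genes$gene, hits, numeric(1), db = db)
  }
  out$databases_hit <- rowSums(out[paste0("n_", DRUG_DATABASES)] > 0)
  out$validated <- out$databases_hit == length(DRUG_DATABASES)
  out$direction_compatible <- NA
  out$rationale <- ""
  rownames(out) <- NULL
  attr(out, "records") <- rec
  class(out) <- c("druggability_calls", "data.frame")
  out
}

#' Check drug mechanisms against the causal direction
#'
#' `direction_compatible` is `TRUE` iff the gene's causal direction is
#' positive and at least one inhibitor-class record exists, or negative and
#' at least one agonist-class record exists.  Modulator, cofactor, and
#' unknown mechanisms never satisfy compatibility.
#'
#' @param calls output of [annotate_targets()].
#' @param records drug-target records (defaults to those attached by
#'   [annotate_targets()]).
#' @return `calls` with `direction_compatible` and `rationale` filled in.
#' @export
direction_compatibility <- function(calls, records = attr(calls, "records")) {
  stopifnot(inherits(calls, "druggability_calls"))
  records$target_key <- toupper(records$target)
  for (i in seq_len(nrow(calls))) {
    mech <- records$mechanism[records$target_key == toupper(calls$gene[i])]
    needed <- if (calls$causal_direction[i] == "positive") "inhibitor" else "agonist"
    ok <- needed %in% mech
    calls$direction_compatible[i] <- ok
    calls$rationale[i] <- if (ok) {
      sprintf("%s causal direction with %s available", calls$causal_direction[i], needed)
    } else if (length(mech) == 0L) {
      "no drug records"
    } else {
      sprintf("%s causal direction but no %s (found: %s)",
              calls$causal_direction[i], needed,
              paste(sort(unique(mech)), collapse = ", "))
    }
  }
  calls
}
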