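#' Published worked-example data shipped with the package
#'
#' `published_mediation_effects()` returns the reported per-gene
#' sepsis-mediated effects on ARDS (estimate, SE, and 95%
#' distribution-of-product confidence limits) for the 50 genes retained by a
#' genome-wide drug-target MR screen, transcribed from the study's published
#' results table.  Together with the published mediator -> outcome effect
#' (`published_mediator_effect()`: beta 1.80, SE 0.36 for sepsis on ARDS on
#' the log-odds scale) these rows drive the worked examples: the
#' gene -> mediator path and its SE can be [back_derive_path()]-derived from
#' each row and the confidence limits recomputed with [dop_ci()].
#'
#' @return data.frame with columns `gene`, `ensembl_id`, `estimate`, `se`,
#'   `ci_low`, `ci_high`.
#' @export
published_mediation_effects <- function() {
  utils::read.delim(
    system.file("extdata", "published_mediation_effects.tsv",
                package = "mrtriage", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname published_mediation_effects
#' @return for `published_mediator_effect()`: list with `beta` and `se`.
#' @export
published_mediator_effect <- function() list(beta = 1.80, se = 0.36)

#' @rdname published_mediation_effects
#' @return for `published_drug_tables()`: named list of the three
#'   drug-target record tables (`drugbank`, `chembl`, `dgidb`) transcribed
#'   from the study's druggability table, each validated by
#'   [read_drug_table()].
#' @export
published_drug_tables <- function() {
  f <- function(name, db) {
    read_drug_table(
      system.file("extdata", name, package = "mrtriage", mustWork = TRUE),
      database = db
    )
  }
  list(drugbank = f("drugbank_targets.tsv", "drugbank"),
       chembl = f("chembl_targets.tsv", "chembl"),
       dgidb = f("dgidb_targets.tsv", "dgidb"))
}
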