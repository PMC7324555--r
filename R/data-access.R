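# Bundled reference tables from the P. putida KT2440 / plasmid RP4
# serial-transfer evolution study, stored as plain TSVs under extdata.

plasfit_extdata <- function(file) {
  system.file("extdata", file, package = "plasfit", mustWork = TRUE)
}

#' Per-strain whole-genome sequencing coverage summaries
#'
#' Read and mean-depth summaries for the ancestral RP4-harboring
#' *P. putida* KT2440 strain and twelve isolates (six large-colony evolved,
#' six small-colony) from a 144-h serial-transfer competition: total reads,
#' reads mapped to chromosome and plasmid, and mean depth of each replicon.
#' The substrate of [copy_number_table()].
#'
#' @return A 13-row tibble.
#' @examples
#' copy_number_table(rp4_coverage())
#' @export
rp4_coverage <- function() {
  read_coverage_table(plasfit_extdata("kt2440_rp4_wgs_coverage.tsv"))
}

#' Differentially transcribed ORFs under sRNA-region overexpression
#'
#' The 33 KT2440 ORFs (27 up, 6 down) called differentially transcribed when
#' a 400-bp chromosomal sRNA region was overexpressed, with locus tags, COG
#' category codes and direction.
#'
#' @return A 33-row tibble: `no`, `gene_name`, `orf_id`, `cog_code`,
#'   `product`, `direction`.
#' @export
kt2440_de_table <- function() {
  out <- read_plasfit_table(plasfit_extdata("kt2440_srna_de_orfs.tsv"),
                            c("orf_id", "cog_code", "direction"))
  out$cog_code <- normalise_cog(out$cog_code)
  out
}

#' Genome-wide COG category counts for *P. putida* KT2440
#'
#' Counts of ORFs per COG functional category over the 5,350-ORF genome
#' annotation (unassigned ORFs under `"-"`), the enrichment background for
#' [tally_by_cog()].
#'
#' @return A 23-row tibble: `cog_code`, `genome_count`.
#' @export
kt2440_cog_genome <- function() {
  out <- read_plasfit_table(plasfit_extdata("kt2440_cog_genome_counts.tsv"),
                            c("cog_code", "genome_count"), "genome_count")
  out$cog_code <- normalise_cog(out$cog_code)
  out
}
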