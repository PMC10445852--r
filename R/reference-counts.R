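#' Published summary counts for the mealworm and red flour beetle genomes
#'
#' Numerator/denominator pairs behind the published assembly and annotation
#' summary tables of the 2021 chromosome-scale *Tenebrio molitor* assembly,
#' its 2020 short-read predecessor, and the *Tribolium castaneum* reference:
#' cumulative sizes and contig counts (mean contig length), BUSCO complete
#' counts out of the 1,367-gene Insecta set, N-base counts, and cumulative
#' coding-sequence sizes. These pairs are the inputs to the table-arithmetic
#' identities (`mean = round(total/n)`, `pct = round(100*count/total, d)`)
#' that the package re-derives; the `printed_*` columns hold the values as
#' published, for comparison.
#'
#' @return named list of data frames: `mean_contig_length`, `busco_percent`,
#'   `n_base_percent`, `coding_fraction`.
#' @export
reference_assembly_counts <- function() {
  list(
    mean_contig_length = data.frame(
      assembly = c("tenebrio_2021", "tenebrio_2020", "tribolium"),
      cumulative_size = c(287931689, 280780514, 165944485),
      n_contigs = c(112, 31390, 2082),
      printed_mean = c(2570819, 8945, 79704)),
    busco_percent = data.frame(
      gene_set = c("tenebrio_2021_genome", "tenebrio_2021_annotation"),
      complete = c(1360, 1319),
      total = c(1367, 1367),
      printed_pct = c(99.5, 96.5)),
    n_base_percent = data.frame(
      assembly = "tenebrio_2021",
      n_count = 28500,
      cumulative_size = 287931689,
      printed_pct = 0.01),
    coding_fraction = data.frame(
      assembly = c("tenebrio_2021", "tribolium"),
      coding_bp = c(25230147, 26681223),
      cumulative_size = c(287931689, 165944485),
      printed_pct = c(8.8, 16.1))
  )
}

#' Re-derive the published table percentages and means
#'
#' Applies the package's rounding arithmetic to every numerator/denominator
#' pair in [reference_assembly_counts()] and reports derived next to
#' published values.
#'
#' @return data frame with `quantity`, `derived`, `printed`, `agrees`.
#' @export
check_reference_arithmetic <- function() {
  rc <- reference_assembly_counts()
  rows <- rbind(
    data.frame(quantity = paste0("mean_contig_length_",
                                 rc$mean_contig_length$assembly),
               derived = round_half_up(rc$mean_contig_length$cumulative_size /
                                         rc$mean_contig_length$n_contigs),
               printed = rc$mean_contig_length$printed_mean),
    data.frame(quantity = paste0("busco_complete_pct_",
                                 rc$busco_percent$gene_set),
               derived = percent_of(rc$busco_percent$complete,
                                    rc$busco_percent$total, 1),
               printed = rc$busco_percent$printed_pct),
    data.frame(quantity = "n_base_pct_tenebrio_2021",
               derived = percent_of(rc$n_base_percent$n_count,
                                    rc$n_base_percent$cumulative_size, 2),
               printed = rc$n_base_percent$printed_pct),
    data.frame(quantity = paste0("coding_pct_", rc$coding_fraction$assembly),
               derived = percent_of(rc$coding_fraction$coding_bp,
                                    rc$coding_fraction$cumulative_size, 1),
               printed = rc$coding_fraction$printed_pct))
  rows$agrees <- rows$derived == rows$printed
  rows
}
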