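#' Allowed network tags
#'
#' The closed vocabulary of brain-network tags used by the region lookup:
#' sensorimotor (SMN), visual (VIS), auditory (AUD), default-mode (DMN),
#' frontoparietal (FPN), cingulo-opercular (CON), cerebellar (CN),
#' subcortical (SUB), attention (ATT), and not-defined (ND).
#' @export
network_tags <- c("SMN", "VIS", "AUD", "DMN", "FPN", "CON", "CN", "SUB",
                  "ATT", "ND")

#' Load a region-to-network lookup table
#'
#' Reads a two-column delimited file (`region_label`, `network`) mapping each
#' parcellation region to one of the ten [network_tags]. With `path = NULL`
#' the packaged default for the 116-region AAL parcellation is returned.
#'
#' The packaged AAL assignment is curated for this package following common
#' network conventions (motor strip to SMN, occipital cortex to VIS, medial
#' default-mode core to DMN, insula/cingulate to CON, basal ganglia and
#' medial temporal structures to SUB, cerebellum and vermis to CN, orbital
#' and temporal-pole regions left ND); it is a synthetic stand-in for
#' study-specific assignments, which are rarely published in full.
#'
#' @param path optional path to a TSV/CSV with columns `region_label` and
#'   `network`; `NULL` loads the packaged AAL-116 table.
#' @return A tibble with columns `region_label` and `network` (factor over
#'   [network_tags]).
#' @examples
#' nets <- load_network_table()
#' dplyr::count(nets, network)
#' @export
load_network_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "aal116_networks.tsv",
                                package = "dynstates", mustWork = TRUE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("region_label", "network") %in% names(df))) {
    abort("network table needs columns `region_label` and `network`")
  }
  if (anyDuplicated(df$region_label)) {
    abort("duplicate region labels in network table")
  }
  bad <- setdiff(unique(df$network), network_tags)
  if (length(bad)) {
    abort(sprintf("unknown network tag(s): %s (allowed: %s)",
                  paste(bad, collapse = ", "),
                  paste(network_tags, collapse = ", ")))
  }
  tibble::tibble(region_label = as.character(df$region_label),
                 network = factor(df$network, levels = network_tags))
}

#' Write a network table to TSV
#' @param networks tibble as returned by [load_network_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_table <- function(networks, path) {
  utils::write.table(
    data.frame(region_label = networks$region_label,
               network = as.character(networks$network)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
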