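#' Load a packaged study table
#'
#' The package ships plain-text transcriptions of the published comparison
#' tables for a pair of congeneric desert-shrub plastomes: genome features
#' (`table1`), indel events (`table3`), nucleotide substitutions (`table4`),
#' per-gene Ts/Tv/S/N counts (`table5`) and SSR loci (`table6`). Obvious
#' typography in the printed originals is carried verbatim where possible
#' and otherwise read plainly, with a non-empty `flag` column marking every
#' such row rather than silently correcting it.
#'
#' @param name one of `"table1"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"table6"`.
#' @return data.frame of typed records.
#' @export
load_paper_fixture <- function(name = c("table1", "table3", "table4",
                                        "table5", "table6")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "plastomeDiff",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("flag" %in% names(df)) df$flag[is.na(df$flag)] <- ""
  if (name == "table6") df$unit_length <- nchar(df$motif)
  df
}
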