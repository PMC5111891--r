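JUNCTION_NAMES <- c("LSC/IRb", "IRb/SSC", "SSC/IRa", "IRa/LSC")

#' Positions of the four single-copy/IR junctions
#'
#' On the canonical rotation (LSC starting at position 1), each junction is
#' reported as the position of the last base of the upstream region, so
#' `IRa/LSC` equals the genome length.
#'
#' @param structure a `QuadripartiteStructure` computed on a canonically
#'   rotated genome (LSC start at 1).
#' @return named integer vector of the four junction positions.
#' @export
junction_positions <- function(structure) {
  stopifnot(inherits(structure, "QuadripartiteStructure"))
  validate_structure(structure)
  reg <- structure$regions
  len <- stats::setNames(reg$length, reg$name)
  if (reg$start[reg$name == "LSC"] != 1L) {
    stop("structure is not canonically rotated (LSC does not start at 1); ",
         "apply canonical_rotation() and re-detect")
  }
  stats::setNames(cumsum(len[c("LSC", "IRb", "SSC", "IRa")]), JUNCTION_NAMES)
}

#' Distance from an IR junction to its nearest gene
#'
#' Counts the bases strictly between a junction and the nearest gene
#' boundary on the single-copy side (a gene touching or crossing the
#' junction gives 0), and lists genes whose span crosses the junction with
#' the length of gene lying inside the IR — the quantities compared across
#' genomes when studying IR expansion and contraction.
#'
#' @param structure a `QuadripartiteStructure` on the canonical rotation.
#' @param features list of [gene_feature()] objects on the same coordinates.
#' @param junction one of `"LSC/IRb"`, `"IRb/SSC"`, `"SSC/IRa"`, `"IRa/LSC"`,
#'   or `NULL` (default) for all four.
#' @return data.frame with one row per junction: `genome_id`, `junction`,
#'   `position`, `nearest_gene`, `distance`, `genes_cut` (comma-separated
#'   `gene:bases_in_IR`, empty when none).
#' @export
junction_gene_distance <- function(structure, features, junction = NULL) {
  jp <- junction_positions(structure)
  which_j <- if (is.null(junction)) JUNCTION_NAMES else match.arg(junction, JUNCTION_NAMES)
  reg <- structure$regions
  L <- structure$total_length
  ft <- features_table(features)
  if (nrow(ft) == 0L) {
    warning("no annotated genes; junction report is empty")
    return(data.frame(genome_id = character(), junction = character(),
                      position = integer(), nearest_gene = character(),
                      distance = integer(), genes_cut = character()))
  }
  rows <- lapply(which_j, function(jn) {
    J <- jp[[jn]]
    # single-copy side and adjacent IR interval for this junction
    sc_left <- jn %in% c("LSC/IRb", "SSC/IRa")  # single-copy region upstream?
    ir_name <- if (jn %in% c("LSC/IRb", "IRb/SSC")) "IRb" else "IRa"
    ir <- reg[reg$name == ir_name, ]
    cross <- if (jn == "IRa/LSC") {
      rep(FALSE, nrow(ft))   # only an origin-wrapping gene could cross; unsupported
    } else {
      ft$start <= J & ft$end >= J + 1L
    }
    cut <- ft[cross, , drop = FALSE]
    cut_str <- if (nrow(cut)) {
      paste(vapply(seq_len(nrow(cut)), function(r) {
        in_ir <- length(intersect(seq.int(cut$start[r], cut$end[r]),
                                  seq.int(ir$start, ir$end)))
        sprintf("%s:%d", cut$name[r], in_ir)
      }, character(1L)), collapse = ",")
    } else ""
    if (nrow(cut)) {
      nearest <- cut$name[1L]; dist <- 0L
    } else if (sc_left) {
      # nearest gene end at or before J
      d <- J - ft$end
      d[d < 0L] <- NA
      i <- which.min(d)
      nearest <- ft$name[i]; dist <- d[i]
    } else {
      # nearest gene start after J (position J+1 is the first SC base;
      # for IRa/LSC the next base wraps to 1)
      from <- if (jn == "IRa/LSC") 0L else J
      d <- ft$start - from - 1L
      d[d < 0L] <- NA
      i <- which.min(d)
      nearest <- ft$name[i]; dist <- d[i]
    }
    data.frame(genome_id = structure$genome_id, junction = jn,
               position = unname(J), nearest_gene = nearest,
               distance = as.integer(dist), genes_cut = cut_str,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Junction comparison table across genomes
#'
#' Runs [junction_gene_distance()] per genome and stacks the rows, one row
#' per genome and junction, for side-by-side comparison of IR border
#' positions among related plastomes.
#'
#' @param structures list of `QuadripartiteStructure` objects.
#' @param features_list list of feature lists, parallel to `structures`.
#' @return combined data.frame.
#' @export
junction_table <- function(structures, features_list) {
  stopifnot(length(structures) == length(features_list))
  do.call(rbind, Map(junction_gene_distance, structures, features_list))
}
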