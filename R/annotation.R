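#' Construct a gene feature
#'
#' A gene feature is a named, stranded set of exon intervals on the plastome,
#' of type CDS, tRNA, rRNA or pseudogene. `rps12`-style trans-spliced genes
#' carry a flag; their "intron" lengths are undefined.
#'
#' @param name gene symbol.
#' @param ftype one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"pseudogene"`.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame (or 2-column matrix) of 1-based inclusive
#'   `start`/`end` intervals.
#' @param trans_spliced logical flag.
#' @return an object of class `GeneFeature`.
#' @export
gene_feature <- function(name, ftype = "CDS", strand = "+", exons,
                         trans_spliced = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ftype <- match.arg(ftype, c("CDS", "tRNA", "rRNA", "pseudogene"))
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  stopifnot(nrow(exons) >= 1L, all(exons$end >= exons$start))
  if (!trans_spliced && nrow(exons) > 1L) {
    if (any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
      stop("overlapping exons in gene ", name)
    }
  }
  rownames(exons) <- NULL
  structure(list(name = name, ftype = ftype, strand = strand,
                 exons = exons, trans_spliced = isTRUE(trans_spliced)),
            class = "GeneFeature")
}

#' @export
print.GeneFeature <- function(x, ...) {
  cat(sprintf("GeneFeature %s [%s, %s] %d exon(s): %s%s\n", x$name, x$ftype,
              x$strand, nrow(x$exons),
              paste(sprintf("%d-%d", x$exons$start, x$exons$end), collapse = ","),
              if (x$trans_spliced) " (trans-spliced)" else ""))
  invisible(x)
}

feature_span <- function(f) c(min(f$exons$start), max(f$exons$end))

#' Flatten a feature list to a data.frame
#'
#' @param features list of [gene_feature()] objects.
#' @return data.frame with one row per gene: name, ftype, strand, start, end,
#'   n_exons, trans_spliced.
#' @export
features_table <- function(features) {
  if (length(features) == 0L) {
    return(data.frame(name = character(), ftype = character(),
                      strand = character(), start = integer(), end = integer(),
                      n_exons = integer(), trans_spliced = logical()))
  }
  do.call(rbind, lapply(features, function(f) {
    sp <- feature_span(f)
    data.frame(name = f$name, ftype = f$ftype, strand = f$strand,
               start = sp[1L], end = sp[2L], n_exons = nrow(f$exons),
               trans_spliced = f$trans_spliced, stringsAsFactors = FALSE)
  }))
}

#' Read gene annotations from GFF3 or GenBank
#'
#' GFF3 is the native dialect (read via rtracklayer). GenBank flat files are
#' accepted read-only through a minimal feature-table reader (gene, CDS,
#' tRNA, rRNA keys; `join()`/`complement()` locations; `/pseudo` qualifier).
#'
#' @param path annotation file.
#' @param fmt `"gff3"` or `"genbank"`; default guessed from the extension.
#' @param genome_length optional; coordinates beyond it are rejected.
#' @return list of [gene_feature()] objects in genomic order.
#' @export
read_annotations <- function(path, fmt = c("auto", "gff3", "genbank"),
                             genome_length = NULL) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "gff3"
  }
  feats <- switch(fmt, gff3 = read_gff3_features(path),
                  genbank = read_genbank_features(path))
  if (!is.null(genome_length)) {
    for (f in feats) {
      if (max(f$exons$end) > genome_length) {
        stop("feature ", f$name, " has coordinates beyond genome length ",
             genome_length)
      }
    }
  }
  ord <- order(vapply(feats, function(f) feature_span(f)[1L], numeric(1L)))
  feats[ord]
}

read_gff3_features <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^##gff-version", first)) {
    stop("missing ##gff-version pragma in ", path)
  }
  df <- as.data.frame(rtracklayer::readGFF(path))
  if (nrow(df) == 0L) return(list())
  get_attr <- function(row, keys) {
    for (k in keys) {
      if (k %in% names(df)) {
        v <- df[[k]][row]
        if (is.list(v)) v <- unlist(v)[1L]
        if (length(v) == 1L && !is.na(v) && nzchar(as.character(v)))
          return(as.character(v))
      }
    }
    NA_character_
  }
  exon_types <- c("CDS", "exon", "tRNA", "rRNA", "pseudogenic_exon")
  gene_types <- c("gene", "pseudogene")
  is_exon <- df$type %in% exon_types
  is_gene <- df$type %in% gene_types

  gene_meta <- list()
  for (r in which(is_gene)) {
    id <- get_attr(r, c("ID", "Name", "gene"))
    gene_meta[[id]] <- list(
      name = get_attr(r, c("Name", "gene", "ID")),
      strand = as.character(df$strand[r]),
      pseudo = df$type[r] == "pseudogene" ||
        identical(tolower(get_attr(r, "biotype")), "pseudogene") ||
        identical(tolower(get_attr(r, "pseudo")), "true"),
      ftype = get_attr(r, "ftype"),
      trans = identical(tolower(get_attr(r, "trans_spliced")), "true")
    )
  }
  keys <- vapply(which(is_exon), function(r) {
    k <- get_attr(r, c("Parent", "ID", "gene", "Name"))
    if (is.na(k)) stop("GFF3 exon-level record at row ", r,
                       " has no Parent/ID/gene attribute")
    k
  }, character(1L))
  feats <- list()
  for (k in unique(keys)) {
    rows <- which(is_exon)[keys == k]
    meta <- gene_meta[[k]]
    ctype <- setdiff(unique(as.character(df$type[rows])), "exon")
    ftype <- if (!is.null(meta) && isTRUE(meta$pseudo)) "pseudogene"
      else if (!is.null(meta) && !is.na(meta$ftype)) meta$ftype
      else if (length(ctype) > 0L && ctype[1L] %in% c("CDS", "tRNA", "rRNA")) ctype[1L]
      else "CDS"
    strand <- if (!is.null(meta)) meta$strand else as.character(df$strand[rows[1L]])
    if (!strand %in% c("+", "-")) strand <- "+"
    nm <- if (!is.null(meta)) meta$name else k
    feats[[length(feats) + 1L]] <- gene_feature(
      nm, ftype, strand,
      data.frame(start = df$start[rows], end = df$end[rows]),
      trans_spliced = !is.null(meta) && isTRUE(meta$trans)
    )
  }
  # genes with no exon-level children (e.g. bare pseudogene records)
  for (id in names(gene_meta)) {
    if (!id %in% keys && !any(vapply(feats, function(f) f$name == gene_meta[[id]]$name, logical(1L)))) {
      r <- which(is_gene)[vapply(which(is_gene), function(rr)
        identical(get_attr(rr, c("ID", "Name", "gene")), id), logical(1L))][1L]
      meta <- gene_meta[[id]]
      feats[[length(feats) + 1L]] <- gene_feature(
        meta$name, if (meta$pseudo) "pseudogene" else "CDS",
        if (meta$strand %in% c("+", "-")) meta$strand else "+",
        data.frame(start = df$start[r], end = df$end[r]),
        trans_spliced = meta$trans
      )
    }
  }
  feats
}

parse_genbank_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- gregexpr("[0-9]+\\.\\.[0-9]+|[0-9]+(?![0-9.])", loc, perl = TRUE)
  toks <- regmatches(loc, nums)[[1L]]
  iv <- do.call(rbind, lapply(toks, function(t) {
    p <- as.integer(strsplit(t, "..", fixed = TRUE)[[1L]])
    if (length(p) == 1L) p <- c(p, p)
    p
  }))
  list(strand = strand,
       exons = data.frame(start = iv[, 1L], end = iv[, 2L]))
}

read_genbank_features <- function(path) {
  lines <- readLines(path)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) stop("not a GenBank flat file (no FEATURES block): ", path)
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1L]]) - 1L else length(lines)
  flines <- lines[(fstart[1L] + 1L):fend]
  keyed <- grepl("^ {5}\\S", flines)
  idx <- cumsum(keyed)
  feats <- list()
  for (b in unique(idx[idx > 0L])) {
    blk <- flines[idx == b]
    key <- sub("^ {5}(\\S+).*$", "\\1", blk[1L])
    if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
    body <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", blk[1L]), blk[-1L])),
                  collapse = "\n")
    parts <- strsplit(body, "\n/", fixed = TRUE)[[1L]]
    loc <- gsub("\\s", "", parts[1L])
    quals <- parts[-1L]
    getq <- function(q) {
      hit <- grep(paste0("^", q, "="), quals, value = TRUE)
      if (length(hit) == 0L) return(NA_character_)
      gsub("^\"|\"$", "", gsub("\n\\s*", " ", sub(paste0("^", q, "="), "", hit[1L])))
    }
    pseudo <- any(grepl("^pseudo(\\s|$)", quals)) || any(quals == "pseudo")
    pl <- parse_genbank_location(loc)
    feats[[length(feats) + 1L]] <- list(
      key = key, name = getq("gene") %||% NA_character_, strand = pl$strand,
      exons = pl$exons, pseudo = pseudo
    )
  }
  # product-level records win over bare gene records of the same name
  out <- list()
  prod <- feats[vapply(feats, function(f) f$key != "gene", logical(1L))]
  genes <- feats[vapply(feats, function(f) f$key == "gene", logical(1L))]
  seen <- character()
  for (f in prod) {
    nm <- if (is.na(f$name)) paste0(f$key, "_", f$exons$start[1L]) else f$name
    ftype <- if (f$pseudo) "pseudogene" else f$key
    out[[length(out) + 1L]] <- gene_feature(nm, ftype, f$strand, f$exons)
    seen <- c(seen, nm)
  }
  for (f in genes) {
    nm <- if (is.na(f$name)) next else f$name
    if (nm %in% seen) {
      if (f$pseudo) {
        i <- which(vapply(out, function(o) o$name == nm, logical(1L)))[1L]
        out[[i]]$ftype <- "pseudogene"
      }
      next
    }
    out[[length(out) + 1L]] <- gene_feature(
      nm, if (f$pseudo) "pseudogene" else "CDS", f$strand, f$exons)
    seen <- c(seen, nm)
  }
  out
}

#' Write gene annotations as GFF3
#'
#' Emits one `gene` line per feature plus one exon-level line (of the
#' feature's type) per exon, with `Parent` links, a `ftype` attribute and a
#' `trans_spliced` flag so [read_annotations()] round-trips exactly.
#'
#' @param features list of [gene_feature()] objects.
#' @param path output file.
#' @param seqid sequence name for column 1 (default `"genome"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seqid = "genome") {
  lines <- "##gff-version 3"
  for (f in features) {
    sp <- feature_span(f)
    gtype <- if (f$ftype == "pseudogene") "pseudogene" else "gene"
    lines <- c(lines, paste(seqid, "plastomeDiff", gtype, sp[1L], sp[2L], ".",
                            f$strand, ".",
                            sprintf("ID=%s;Name=%s;ftype=%s;trans_spliced=%s",
                                    f$name, f$name, f$ftype,
                                    tolower(f$trans_spliced)),
                            sep = "\t"))
    etype <- if (f$ftype == "pseudogene") "pseudogenic_exon" else f$ftype
    for (e in seq_len(nrow(f$exons))) {
      lines <- c(lines, paste(seqid, "plastomeDiff", etype,
                              f$exons$start[e], f$exons$end[e], ".",
                              f$strand, if (etype == "CDS") "0" else ".",
                              sprintf("ID=%s.exon%d;Parent=%s", f$name, e, f$name),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Classify a genomic position as coding, intron or intergenic
#'
#' Coding if the position lies inside any exon (the smallest enclosing exon
#' wins, ties broken by earlier gene start; tRNA/rRNA exons count as coding);
#' Intron if inside a gene's span but no exon; otherwise Intergenic with the
#' nearest flanking genes, circular at the origin, as context
#' `"upstream-downstream"`.
#'
#' @param pos 1-based position (vectorized).
#' @param features list of [gene_feature()] objects.
#' @param genome_length total genome length (needed for circular flanking
#'   context; defaults to the maximum annotated coordinate).
#' @return data.frame with columns `pos`, `category`, `context`.
#' @export
classify_position <- function(pos, features, genome_length = NULL) {
  ft <- features_table(features)
  if (is.null(genome_length)) genome_length <- max(1L, ft$end)
  stopifnot(all(pos >= 1L), all(pos <= genome_length))
  one <- function(p) {
    hit_gene <- NA_character_; hit_size <- Inf; hit_start <- Inf
    intron_gene <- NA_character_
    for (f in features) {
      ex <- f$exons
      inside <- p >= ex$start & p <= ex$end
      if (any(inside)) {
        sz <- min(ex$end[inside] - ex$start[inside] + 1L)
        st <- feature_span(f)[1L]
        if (sz < hit_size || (sz == hit_size && st < hit_start)) {
          hit_gene <- f$name; hit_size <- sz; hit_start <- st
        }
      } else {
        sp <- feature_span(f)
        if (!f$trans_spliced && p >= sp[1L] && p <= sp[2L] && is.na(intron_gene)) {
          intron_gene <- f$name
        }
      }
    }
    if (!is.na(hit_gene)) return(c("Coding", hit_gene))
    if (!is.na(intron_gene)) return(c("Intron", paste(intron_gene, "intron")))
    if (nrow(ft) == 0L) return(c("Intergenic", "NA-NA"))
    dup <- (p - ft$end) %% genome_length      # distance to gene ends, upstream
    ddn <- (ft$start - p) %% genome_length    # distance to gene starts, downstream
    c("Intergenic", paste0(ft$name[which.min(dup)], "-", ft$name[which.min(ddn)]))
  }
  res <- t(vapply(pos, one, character(2L)))
  data.frame(pos = pos, category = res[, 1L], context = res[, 2L],
             stringsAsFactors = FALSE)
}

#' Exon/intron length inventory of intron-containing genes
#'
#' For each multi-exon gene, exon lengths and intervening intron lengths in
#' transcript order (reversed for minus-strand genes). Trans-spliced genes
#' report exon lengths with intron lengths `NA` (their "introns" are not a
#' contiguous genomic segment).
#'
#' @param features list of [gene_feature()] objects.
#' @return data.frame with columns `gene`, `ftype`, `n_exons` and list
#'   columns `exon_lengths`, `intron_lengths`.
#' @export
intron_inventory <- function(features) {
  multi <- Filter(function(f) nrow(f$exons) > 1L, features)
  rows <- lapply(multi, function(f) {
    ex <- f$exons
    elen <- ex$end - ex$start + 1L
    ilen <- if (f$trans_spliced) rep(NA_integer_, nrow(ex) - 1L)
      else ex$start[-1L] - ex$end[-nrow(ex)] - 1L
    if (f$strand == "-") { elen <- rev(elen); ilen <- rev(ilen) }
    data.frame(gene = f$name, ftype = f$ftype, n_exons = nrow(ex),
               exon_lengths = I(list(elen)), intron_lengths = I(list(ilen)),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), ftype = character(),
                      n_exons = integer(),
                      exon_lengths = I(list()), intron_lengths = I(list())))
  }
  do.call(rbind, rows)
}
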