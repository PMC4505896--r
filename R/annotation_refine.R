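#' Feature tables for annotation refinement
#'
#' Refinement works on plain data.frames of genomic intervals with columns
#' `chrom`, `start`, `end` (0-based half-open internally; GFF3 conversion
#' happens only at I/O boundaries), `family`, and optionally `order`,
#' `score`, `strand`. Strand is carried through but ignored by all
#' refinement rules.
#'
#' @param chrom,start,end,family,order,score,strand feature columns;
#'   `start`/`end` 0-based half-open with `start < end`.
#' @return data.frame of class `te_features`.
#' @export
feature_table <- function(chrom, start, end, family,
                          order = NA_character_, score = NA_real_,
                          strand = "*") {
  d <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), family = as.character(family),
                  order = order, score = score, strand = strand,
                  stringsAsFactors = FALSE)
  validate_features(d)
  class(d) <- c("te_features", "data.frame")
  d
}

validate_features <- function(d) {
  req <- c("chrom", "start", "end", "family")
  if (!all(req %in% names(d)))
    stop("feature table needs columns: ", paste(req, collapse = ", "))
  if (any(d$end <= d$start)) stop("feature with end <= start")
  invisible(d)
}

as_granges <- function(d, seqlevels = unique(d$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(d$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end))
}

#' Remove TE features heavily overlapped by microsatellites
#'
#' Microsatellite runs inside TE consensus sequences produce spurious TE
#' calls. A TE feature is removed when the union of its
#' microsatellite-overlapped bases covers at least `max_frac` of its
#' length (intersect-tool overlap-fraction semantics, so exactly 30%
#' coverage is removed at the default threshold).
#'
#' @param tes,microsats feature tables in the same coordinate convention.
#' @param max_frac removal threshold on the covered fraction, default 0.3.
#' @return Filtered TE feature table.
#' @export
filter_microsatellite_overlap <- function(tes, microsats, max_frac = 0.3) {
  validate_features(tes)
  if (nrow(tes) == 0 || is.null(microsats) || nrow(microsats) == 0)
    return(tes)
  validate_features(microsats)
  lv <- union(unique(tes$chrom), unique(microsats$chrom))
  q <- as_granges(tes, lv)
  s <- GenomicRanges::reduce(as_granges(microsats, lv))
  hits <- GenomicRanges::findOverlaps(q, s)
  covered <- numeric(nrow(tes))
  if (length(hits) > 0) {
    inter <- GenomicRanges::pintersect(
      q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)])
    wsum <- tapply(GenomicRanges::width(inter),
                   S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(wsum))] <- as.numeric(wsum)
  }
  keep <- covered < max_frac * (tes$end - tes$start)
  res <- tes[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge and link fragmented same-family TE annotations
#'
#' Overlapping or abutting features of the same family on the same
#' chromosome are merged unconditionally. Remaining disjoint fragments
#' are then chained in position order: two adjacent fragments are linked
#' when the gap penalty is smaller than the score contribution of the
#' smaller fragment, i.e. when
#' `mismatch_penalty * gap < match_score * min(len_left, len_right)`
#' (strict). Each chain is emitted as one feature spanning its extremes,
#' with `score` set to
#' `match_score * sum(fragment lengths) - mismatch_penalty * sum(gaps)`.
#'
#' @param features feature table.
#' @param match_score per-base score of annotated sequence, default 1.
#' @param mismatch_penalty per-base penalty of linked gaps, default 0.5.
#' @return Merged/linked feature table.
#' @export
merge_link_same_family <- function(features, match_score = 1,
                                   mismatch_penalty = 0.5) {
  validate_features(features)
  if (nrow(features) == 0) return(features)
  key <- paste(features$chrom, features$family, sep = "\r")
  parts <- lapply(split(seq_len(nrow(features)), key), function(idx) {
    d <- features[idx, , drop = FALSE]
    r <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    st <- IRanges::start(r) - 1L
    en <- IRanges::end(r)
    o <- order(st)
    st <- st[o]; en <- en[o]
    len <- en - st
    k <- length(st)
    if (k == 1) {
      chain <- rep(1L, 1)
    } else {
      gaps <- st[-1] - en[-k]
      link <- mismatch_penalty * gaps <
        match_score * pmin(len[-k], len[-1])
      chain <- cumsum(c(1L, as.integer(!link)))
    }
    out <- do.call(rbind, lapply(split(seq_len(k), chain), function(ix) {
      cs <- st[ix[1]]; ce <- en[ix[length(ix)]]
      sc <- match_score * sum(len[ix]) -
        if (length(ix) > 1)
          mismatch_penalty * sum(st[ix[-1]] - en[ix[-length(ix)]])
        else 0
      data.frame(chrom = d$chrom[1], start = cs, end = ce,
                 family = d$family[1],
                 order = if ("order" %in% names(d)) d$order[1] else NA,
                 score = sc,
                 strand = if ("strand" %in% names(d)) d$strand[1] else "*")
    }))
    out
  })
  res <- do.call(rbind, parts)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("te_features", "data.frame")
  res
}

#' Resolve overlaps between features of different families
#'
#' Features are processed in decreasing length order (ties broken by
#' chromosome, start coordinate, then family name); each feature is
#' truncated to the bases not already claimed by longer features, a
#' feature whose claimed region splits it yields one piece per remaining
#' run, and features truncated to zero length are dropped. The output is
#' non-overlapping.
#'
#' @param features feature table (same-family merging should already have
#'   been applied).
#' @return Non-overlapping feature table.
#' @export
resolve_cross_family_overlaps <- function(features) {
  validate_features(features)
  if (nrow(features) == 0) return(features)
  len <- features$end - features$start
  o <- order(-len, features$chrom, features$start, features$family)
  claimed <- list()
  pieces <- vector("list", nrow(features))
  for (j in seq_along(o)) {
    i <- o[j]
    ch <- features$chrom[i]
    r <- IRanges::IRanges(features$start[i] + 1L, features$end[i])
    if (!is.null(claimed[[ch]]))
      r <- IRanges::setdiff(r, claimed[[ch]])
    if (length(r) > 0) {
      claimed[[ch]] <- if (is.null(claimed[[ch]])) r
        else IRanges::reduce(c(claimed[[ch]], r))
      p <- features[rep(i, length(r)), , drop = FALSE]
      p$start <- IRanges::start(r) - 1L
      p$end <- IRanges::end(r)
      pieces[[j]] <- p
    }
  }
  res <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("te_features", "data.frame")
  res
}

#' Drop features below a minimum length
#'
#' @param features feature table.
#' @param min_len minimum length in bp (inclusive), default 100.
#' @return Filtered feature table.
#' @export
filter_min_length <- function(features, min_len = 100) {
  validate_features(features)
  res <- features[(features$end - features$start) >= min_len, ,
                  drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full annotation-refinement pipeline
#'
#' Microsatellite filter, same-family merge/link, cross-family overlap
#' resolution, then minimum-length filter — the post-processing applied
#' to a raw repeat annotation before insertion calling.
#'
#' @param tes raw TE feature table.
#' @param microsats microsatellite feature table (NULL to skip the
#'   filter).
#' @param max_frac,match_score,mismatch_penalty,min_len stage parameters;
#'   see the individual stage functions.
#' @return Refined feature table.
#' @export
refine_annotation <- function(tes, microsats = NULL, max_frac = 0.3,
                              match_score = 1, mismatch_penalty = 0.5,
                              min_len = 100) {
  out <- filter_microsatellite_overlap(tes, microsats, max_frac)
  out <- merge_link_same_family(out, match_score, mismatch_penalty)
  out <- resolve_cross_family_overlaps(out)
  filter_min_length(out, min_len)
}

#' Link orthologous genome-alignment blocks across small gaps
#'
#' TE masking before whole-genome alignment leaves gaps at insertion
#' sites; consecutive co-linear blocks on the same chromosome pair are
#' merged when the gap does not exceed `max_gap` in both genomes.
#' Merging is transitive.
#'
#' @param blocks data.frame with columns `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB` (0-based half-open internally).
#' @param max_gap maximum bridged gap in bp on each side, default 20000.
#' @return Merged block table.
#' @export
link_orthologous_blocks <- function(blocks, max_gap = 20000) {
  req <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  if (!all(req %in% names(blocks)))
    stop("block table needs columns: ", paste(req, collapse = ", "))
  if (nrow(blocks) == 0) return(blocks)
  key <- paste(blocks$chromA, blocks$chromB, sep = "\r")
  parts <- lapply(split(blocks, key), function(d) {
    d <- d[order(d$startA), , drop = FALSE]
    cur <- d[1, , drop = FALSE]
    out <- list()
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      gapA <- d$startA[i] - cur$endA
      gapB <- d$startB[i] - cur$endB
      if (gapA <= max_gap && gapB <= max_gap) {
        cur$endA <- max(cur$endA, d$endA[i])
        cur$endB <- max(cur$endB, d$endB[i])
        cur$startB <- min(cur$startB, d$startB[i])
      } else {
        out[[length(out) + 1]] <- cur
        cur <- d[i, , drop = FALSE]
      }
    }
    out[[length(out) + 1]] <- cur
    do.call(rbind, out)
  })
  res <- do.call(rbind, parts)
  res <- res[order(res$chromA, res$startA), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read / write TE feature tables as GFF3
#'
#' On disk, GFF3 uses 1-based inclusive coordinates; in memory the
#' package uses 0-based half-open. The TE family is stored in the `Name`
#' attribute and the order (LTR, non-LTR, TIR) in the `te_order`
#' attribute.
#'
#' @param path GFF3 file path.
#' @param features feature table to write.
#' @return `read_te_gff` returns a `te_features` data.frame.
#' @export
read_te_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  fam <- if ("Name" %in% names(mc)) as.character(mc$Name)
         else as.character(seq_along(gr))
  ord <- if ("te_order" %in% names(mc)) as.character(mc$te_order)
         else NA_character_
  sc <- if ("score" %in% names(mc)) as.numeric(mc$score) else NA_real_
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  family = fam, order = ord, score = sc,
                  strand = as.character(GenomicRanges::strand(gr)),
                  stringsAsFactors = FALSE)
  validate_features(d)
  class(d) <- c("te_features", "data.frame")
  d
}

#' @rdname read_te_gff
#' @export
write_te_gff <- function(features, path) {
  validate_features(features)
  gr <- as_granges(features)
  strand_chr <- if ("strand" %in% names(features))
    features$strand else rep("*", nrow(features))
  strand_chr[!strand_chr %in% c("+", "-")] <- "*"
  GenomicRanges::strand(gr) <- strand_chr
  mc <- S4Vectors::DataFrame(
    source = "TEpopdyn",
    type = ifelse(is.na(features$order) | features$order == "",
                  "dispersed_repeat", features$order),
    score = if ("score" %in% names(features)) features$score else NA_real_,
    Name = features$family,
    te_order = features$order,
    ID = sprintf("te%05d", seq_len(nrow(features))))
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write TE feature tables as BED
#'
#' BED uses 0-based half-open coordinates on disk (same as the in-memory
#' convention); the family is stored in the `name` column. Order
#' information is not representable in BED and is read back as NA.
#'
#' @param path BED file path.
#' @param features feature table to write.
#' @return `read_te_bed` returns a `te_features` data.frame.
#' @export
read_te_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  mc <- S4Vectors::mcols(gr)
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  family = if ("name" %in% names(mc))
                    as.character(mc$name) else as.character(seq_along(gr)),
                  order = NA_character_,
                  score = if ("score" %in% names(mc))
                    as.numeric(mc$score) else NA_real_,
                  strand = as.character(GenomicRanges::strand(gr)),
                  stringsAsFactors = FALSE)
  validate_features(d)
  class(d) <- c("te_features", "data.frame")
  d
}

#' @rdname read_te_bed
#' @export
write_te_bed <- function(features, path) {
  validate_features(features)
  gr <- as_granges(features)
  strand_chr <- if ("strand" %in% names(features))
    features$strand else rep("*", nrow(features))
  strand_chr[!strand_chr %in% c("+", "-")] <- "*"
  GenomicRanges::strand(gr) <- strand_chr
  sc <- if ("score" %in% names(features)) features$score else NA_real_
  sc[is.na(sc)] <- 0
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = features$family,
                                               score = sc)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write orthologous-block tables as TSV
#'
#' On disk, 1-based inclusive coordinates with columns chromA, startA,
#' endA, chromB, startB, endB; in memory 0-based half-open.
#'
#' @param path TSV file path.
#' @param blocks block table to write.
#' @return `read_blocks` returns a data.frame.
#' @export
read_blocks <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  req <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  if (!all(req %in% names(d)))
    stop("block TSV must have columns: ", paste(req, collapse = ", "))
  d$startA <- d$startA - 1L
  d$startB <- d$startB - 1L
  d
}

#' @rdname read_blocks
#' @export
write_blocks <- function(blocks, path) {
  d <- as.data.frame(blocks)
  d$startA <- d$startA + 1L
  d$startB <- d$startB + 1L
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
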