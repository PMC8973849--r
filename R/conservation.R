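#' Classify gene-body bases as coding exon, UTR or intron
#'
#' Splicing makes region annotation ambiguous, so classification is by
#' per-base precedence across all protein-coding transcripts of a gene:
#' every base annotated as coding sequence in any protein-coding transcript
#' is a coding exon; bases annotated as UTR in any such transcript are UTR
#' unless they are also coding sequence; all remaining gene-body bases are
#' introns. A transcript counts as protein-coding when it has at least one
#' CDS feature.
#'
#' @param gff Path to a GFF3 file (1-based inclusive, read with
#'   \pkg{rtracklayer}) or a `GRanges` of its features with `type`, `ID` and
#'   `Parent` metadata.
#'
#' @return Tibble of merged same-class runs: `chrom`, `start`, `end`
#'   (0-based half-open), `width`, `region_class`
#'   (`coding_exon`/`utr`/`intron`), `gene_id`, `region_id`.
#' @export
classify_regions <- function(gff) {
  gr <- if (is.character(gff)) rtracklayer::import(gff, format = "gff3") else gff
  type <- as.character(gr$type)
  ids <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  parents <- gr$Parent
  parent1 <- vapply(as.list(parents), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))

  gene_idx <- type == "gene"
  tx_types <- c("mRNA", "transcript")
  tx_idx <- type %in% tx_types
  tx_gene <- setNames(parent1[tx_idx], ids[tx_idx])

  cds_idx <- type == "CDS"
  utr_idx <- type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")
  coding_tx <- unique(parent1[cds_idx])

  feature_gene <- function(idx, only_coding_tx = FALSE) {
    if (only_coding_tx) idx <- idx & parent1 %in% coding_tx
    par <- parent1[idx]
    g <- ifelse(par %in% names(tx_gene), tx_gene[par], par)
    list(idx = which(idx), gene = unname(g))
  }

  cds <- feature_gene(cds_idx)
  utr <- feature_gene(utr_idx, only_coding_tx = TRUE)

  genes <- if (any(gene_idx)) {
    tibble(gene_id = ids[gene_idx],
           chrom = as.character(GenomicRanges::seqnames(gr)[gene_idx]),
           start = GenomicRanges::start(gr)[gene_idx],
           end = GenomicRanges::end(gr)[gene_idx])
  } else {
    # fall back to the span of each gene's transcripts
    tibble(gene_id = unname(tx_gene),
           chrom = as.character(GenomicRanges::seqnames(gr)[tx_idx]),
           start = GenomicRanges::start(gr)[tx_idx],
           end = GenomicRanges::end(gr)[tx_idx]) |>
      group_by(.data$gene_id, .data$chrom) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
  }

  per_gene <- function(gid) {
    body <- genes[genes$gene_id == gid, ]
    body_gr <- GenomicRanges::GRanges(
      body$chrom, IRanges::IRanges(body$start, body$end))
    pick <- function(fg) {
      sel <- fg$idx[fg$gene == gid]
      gx <- GenomicRanges::granges(gr[sel])
      # set arithmetic below must ignore strand
      GenomicRanges::strand(gx) <- "*"
      GenomicRanges::reduce(gx)
    }
    cds_gr <- pick(cds)
    utr_gr <- GenomicRanges::setdiff(pick(utr), cds_gr)
    intron_gr <- GenomicRanges::setdiff(
      GenomicRanges::setdiff(body_gr, cds_gr), utr_gr)
    to_tbl <- function(g, cls) {
      if (!length(g)) return(tibble())
      tibble(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g) - 1L,  # to 0-based half-open
             end = GenomicRanges::end(g),
             width = GenomicRanges::width(g),
             region_class = cls, gene_id = gid)
    }
    bind_rows(to_tbl(cds_gr, "coding_exon"), to_tbl(utr_gr, "utr"),
              to_tbl(intron_gr, "intron"))
  }

  out <- purrr::map_dfr(unique(genes$gene_id), per_gene) |>
    arrange(.data$gene_id, .data$chrom, .data$start)
  if (nrow(out)) {
    out$region_id <- sprintf("%s:%s:%d-%d:%s", out$gene_id, out$chrom,
                             out$start, out$end, out$region_class)
  } else {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  width = integer(), region_class = character(),
                  gene_id = character(), region_id = character())
  }
  out
}

#' Read a pairwise MAF alignment
#'
#' Minimal reader for pairwise MAF blocks ("a" lines followed by two "s"
#' lines, reference first). Coordinates follow the MAF spec: 0-based starts,
#' sizes in nongap bases, minus-strand starts counted from the reverse
#' strand.
#'
#' @param path MAF file path.
#' @return List of blocks; each block is a list with `ref` and `qry`, each
#'   holding `src`, `start`, `size`, `strand`, `srcsize`, `text`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur <- NULL
  parse_s <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    list(src = f[2], start = as.numeric(f[3]), size = as.numeric(f[4]),
         strand = f[5], srcsize = as.numeric(f[6]), text = f[7])
  }
  for (l in lines) {
    if (grepl("^a", l)) {
      if (!is.null(cur) && length(cur) >= 2) {
        blocks[[length(blocks) + 1L]] <- list(ref = cur[[1]], qry = cur[[2]])
      }
      cur <- list()
    } else if (grepl("^s ", l) || grepl("^s\t", l)) {
      cur[[length(cur) + 1L]] <- parse_s(l)
    }
  }
  if (!is.null(cur) && length(cur) >= 2) {
    blocks[[length(blocks) + 1L]] <- list(ref = cur[[1]], qry = cur[[2]])
  }
  blocks
}

# For one block: 0-based + strand reference positions where the aligned
# query base matches the reference base.
block_match_positions <- function(block, count_softmasked = TRUE) {
  ref_chars <- strsplit(block$ref$text, "")[[1]]
  qry_chars <- strsplit(block$qry$text, "")[[1]]
  if (length(ref_chars) != length(qry_chars)) {
    abort("malformed MAF block: sequences differ in alignment length.")
  }
  nongap <- ref_chars != "-"
  idx <- cumsum(nongap)  # 1..size along reference
  if (identical(block$ref$strand, "-")) {
    pos <- block$ref$srcsize - block$ref$start - idx
  } else {
    pos <- block$ref$start + idx - 1
  }
  eligible <- nongap & qry_chars != "-"
  if (!count_softmasked) {
    eligible <- eligible & ref_chars %in% c("A", "C", "G", "T", "N") &
      qry_chars %in% c("A", "C", "G", "T", "N")
  }
  match <- eligible & toupper(ref_chars) == toupper(qry_chars) &
    toupper(ref_chars) %in% c("A", "C", "G", "T")
  pos[match]
}

maf_chrom <- function(src) sub("^[^.]*\\.", "", src)

#' Percent identity of regions in a pairwise alignment
#'
#' Counts, per region, the aligned columns where reference and query carry
#' the identical nucleotide (case-insensitive by default) and divides by the
#' region's reference length: unaligned or gapped reference bases contribute
#' zero matches but full length, so identity reflects both substitution and
#' alignability. `identity = matches * 100 / length`.
#'
#' @param maf A MAF path or the result of [read_maf()].
#' @param regions Region tibble from [classify_regions()] (0-based
#'   half-open `chrom`, `start`, `end`).
#' @param count_softmasked Count soft-masked (lowercase) columns as
#'   eligible matches (default TRUE).
#'
#' @return `regions` with added `aligned_matches` and `identity` (percent).
#' @export
region_identity <- function(maf, regions, count_softmasked = TRUE) {
  if (is.character(maf)) maf <- read_maf(maf)
  regions <- as_tibble(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))

  by_chrom <- list()
  for (b in maf) {
    ch <- maf_chrom(b$ref$src)
    pos <- block_match_positions(b, count_softmasked)
    by_chrom[[ch]] <- c(by_chrom[[ch]], pos)
  }
  by_chrom <- lapply(by_chrom, function(p) sort(unique(p)))

  chroms_missing <- setdiff(unique(regions$chrom),
                            c(names(by_chrom),
                              vapply(maf, function(b) maf_chrom(b$ref$src),
                                     character(1))))
  if (length(chroms_missing)) {
    warn(paste0("chromosome(s) absent from alignment: ",
                paste(chroms_missing, collapse = ", "),
                "; identity reported as 0."))
  }

  matches <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    p <- by_chrom[[regions$chrom[i]]]
    if (is.null(p)) next
    matches[i] <- sum(p >= regions$start[i] & p < regions$end[i])
  }
  regions$aligned_matches <- matches
  regions$identity <- matches * 100 / (regions$end - regions$start)
  regions
}

#' Percent of a population strictly more conserved than a focal region
#'
#' @param focal Focal identity (percent), a single number.
#' @param population Identity values of the comparison population (the focal
#'   region itself should not be among them).
#'
#' @return `100 * |{identity > focal}| / |population|`.
#' @examples
#' percentile_exceeding(95, c(80, 90, 99)) # 33.33
#' @export
percentile_exceeding <- function(focal, population) {
  if (!length(population)) abort("`population` must be non-empty.")
  if (length(focal) != 1L || !is.finite(focal)) {
    abort("`focal` must be a single finite identity.")
  }
  100 * sum(population > focal) / length(population)
}

#' Rank a focal region's conservation against a region class population
#'
#' @param identities Output of [region_identity()].
#' @param focal_region_id `region_id` of the focal region (excluded from
#'   the population).
#' @param region_class Optional class to restrict the population to (e.g.
#'   compare a focal exon against all coding exons).
#' @return One-row tibble with the focal identity, population size and the
#'   percent of the population strictly exceeding it.
#' @export
conservation_percentile <- function(identities, focal_region_id,
                                    region_class = NULL) {
  identities <- as_tibble(identities)
  focal <- filter(identities, .data$region_id == focal_region_id)
  if (nrow(focal) != 1L) abort("focal region not found (or not unique).")
  pop <- filter(identities, .data$region_id != focal_region_id)
  if (!is.null(region_class)) {
    cls <- region_class
    pop <- filter(pop, .data$region_class == cls)
  }
  tibble(region_id = focal_region_id, identity = focal$identity,
         population = nrow(pop),
         pct_exceeding = percentile_exceeding(focal$identity, pop$identity))
}
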