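#' Configuration for the toy two-genome generator
#'
#' Describes one gene per chromosome as a contiguous tiling of classified
#' regions (coding exon / UTR / intron), each with a target percent
#' identity to a second genome. The generator realizes each target exactly
#' by substituting the required number of bases, so the conservation module
#' can be tested by equality.
#'
#' @param regions Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `region_class` in `coding_exon`/`utr`/`intron`, and
#'   `identity` (target percent, 0-100). Regions must tile each chromosome's
#'   gene body contiguously without overlap, and `width * (100 - identity) /
#'   100` must be an integer (otherwise the target is unreachable and an
#'   error is raised).
#' @param placement `"deterministic"` spaces substituted positions evenly
#'   within a region; `"random"` samples them (seeded).
#' @param seed Integer seed (used for the reference sequence and, in random
#'   placement, the substitution positions).
#'
#' @return A `toy_genome_config` list.
#' @seealso [sim_toy_genomes()]
#' @export
toy_genome_config <- function(regions,
                              placement = c("deterministic", "random"),
                              seed = NULL) {
  placement <- match.arg(placement)
  regions <- as_tibble(regions)
  req <- c("chrom", "start", "end", "region_class", "identity")
  if (!all(req %in% names(regions))) {
    abort(paste0("`regions` needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(regions$end <= regions$start) || any(regions$start < 0)) {
    abort("regions must have end > start >= 0.")
  }
  check_prob(regions$identity, "identity", lo = 0, hi = 100)
  if (!all(regions$region_class %in% c("coding_exon", "utr", "intron"))) {
    abort("region_class must be coding_exon, utr or intron.")
  }
  width <- regions$end - regions$start
  mism <- width * (100 - regions$identity) / 100
  off <- abs(mism - round(mism))
  if (any(off > 1e-9)) {
    bad <- which(off > 1e-9)[1]
    abort(sprintf(
      "identity %g%% is unreachable for a region of length %d (non-integer mismatch count).",
      regions$identity[bad], width[bad]))
  }
  for (ch in unique(regions$chrom)) {
    r <- arrange(filter(regions, .data$chrom == ch), .data$start)
    if (any(r$start[-1] != r$end[-nrow(r)])) {
      abort(sprintf("regions on %s must tile contiguously.", ch))
    }
  }
  structure(list(regions = arrange(regions, .data$chrom, .data$start),
                 placement = placement, seed = seed),
            class = "toy_genome_config")
}

write_gff3 <- function(regions, path) {
  lines <- "##gff-version 3"
  for (ch in unique(regions$chrom)) {
    r <- filter(regions, .data$chrom == ch)
    gid <- paste0("gene_", ch)
    tid <- paste0("tx_", ch)
    g1 <- min(r$start) + 1L  # to 1-based inclusive
    g2 <- max(r$end)
    feat <- function(type, s, e, attrs) {
      sprintf("%s\ttoy\t%s\t%d\t%d\t.\t+\t%s\t%s", ch, type, s, e,
              if (type == "CDS") "0" else ".", attrs)
    }
    lines <- c(lines,
               feat("gene", g1, g2, sprintf("ID=%s", gid)),
               feat("mRNA", g1, g2, sprintf("ID=%s;Parent=%s", tid, gid)))
    exonic <- filter(r, .data$region_class != "intron")
    for (i in seq_len(nrow(exonic))) {
      s <- exonic$start[i] + 1L
      e <- exonic$end[i]
      lines <- c(lines, feat("exon", s, e,
                             sprintf("ID=exon_%s_%d;Parent=%s", ch, i, tid)))
      type <- if (exonic$region_class[i] == "coding_exon") "CDS"
        else "five_prime_UTR"
      lines <- c(lines, feat(type, s, e,
                             sprintf("ID=%s_%s_%d;Parent=%s",
                                     tolower(type), ch, i, tid)))
    }
  }
  writeLines(lines, path)
  path
}

write_maf <- function(chrom_seqs, path, ref_genome = "toyref",
                      qry_genome = "toyqry") {
  lines <- "##maf version=1"
  for (ch in names(chrom_seqs)) {
    ref <- chrom_seqs[[ch]]$ref
    qry <- chrom_seqs[[ch]]$qry
    len <- nchar(ref)
    lines <- c(lines, "", "a score=0.0",
               sprintf("s %s.%s 0 %d + %d %s", ref_genome, ch, len, len, ref),
               sprintf("s %s.%s 0 %d + %d %s", qry_genome, ch, len, len, qry))
  }
  writeLines(lines, path)
  path
}

#' Generate a toy annotated genome pair with controlled identity
#'
#' Builds a random reference sequence per chromosome, a second genome that
#' differs from it by exactly the number of substitutions implied by each
#' region's target identity, a GFF3 annotation whose per-base
#' classification reproduces the configured regions, and a pairwise MAF
#' alignment of the two genomes (full-length, gap-free blocks).
#'
#' @param config A [toy_genome_config()].
#' @param dir Output directory (created if needed); `toy.gff3` and
#'   `toy.maf` are written there.
#'
#' @return List of class `toy_genome_sim`: `gff` and `maf` (file paths),
#'   `truth` (the region tibble with its target identities, plus
#'   `region_id` in the format used by [classify_regions()]) and
#'   `sequences`.
#' @export
sim_toy_genomes <- function(config, dir = tempfile("toygenomes")) {
  stopifnot(inherits(config, "toy_genome_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    regions <- config$regions
    bases <- c("A", "C", "G", "T")
    rotate <- setNames(c("C", "G", "T", "A"), bases)
    chrom_seqs <- list()
    for (ch in unique(regions$chrom)) {
      r <- filter(regions, .data$chrom == ch)
      len <- max(r$end)
      ref <- sample(bases, len, replace = TRUE)
      qry <- ref
      for (i in seq_len(nrow(r))) {
        width <- r$end[i] - r$start[i]
        n_mm <- as.integer(round(width * (100 - r$identity[i]) / 100))
        if (n_mm == 0L) next
        offs <- if (config$placement == "deterministic") {
          unique(floor(seq(0, width - 1, length.out = n_mm)))
        } else {
          sort(sample.int(width, n_mm) - 1L)
        }
        # even spacing can collide after floor(); fill deterministically
        if (length(offs) < n_mm) {
          extra <- setdiff(seq_len(width) - 1L, offs)[seq_len(n_mm - length(offs))]
          offs <- sort(c(offs, extra))
        }
        pos <- r$start[i] + offs + 1L  # 1-based into the sequence vector
        qry[pos] <- rotate[ref[pos]]
      }
      chrom_seqs[[ch]] <- list(ref = paste(ref, collapse = ""),
                               qry = paste(qry, collapse = ""))
    }
    gff_path <- write_gff3(regions, file.path(dir, "toy.gff3"))
    maf_path <- write_maf(chrom_seqs, file.path(dir, "toy.maf"))
    truth <- regions |>
      mutate(gene_id = paste0("gene_", .data$chrom),
             region_id = sprintf("%s:%s:%d-%d:%s", .data$gene_id,
                                 .data$chrom, .data$start, .data$end,
                                 .data$region_class))
    structure(list(gff = gff_path, maf = maf_path, truth = truth,
                   sequences = chrom_seqs, config = config),
              class = "toy_genome_sim")
  })
}
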