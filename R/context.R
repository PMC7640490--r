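# Genomic context of insertion sites: repeat axis (simple repeat / SINE /
# LINE / other repeat / non-repeated) and genic axis (exonic / intronic /
# intergenic), answered by interval queries on annotation tracks.

REPEAT_CLASSES <- c("simple_repeat", "sine", "line", "other_repeat", "non_repeated")
GENIC_CLASSES <- c("exonic", "intronic", "intergenic")

#' Build an annotation track set
#'
#' @param simple_repeats,sines,lines,other_repeats,exons,introns `GRanges`
#'   (any may be empty).
#' @param genome_lengths named numeric vector of chromosome lengths (used by
#'   [genome_fraction()]).
#' @return an `annotation_tracks` list of `GRanges`.
#' @export
annotation_tracks <- function(simple_repeats = GenomicRanges::GRanges(),
                              sines = GenomicRanges::GRanges(),
                              lines = GenomicRanges::GRanges(),
                              other_repeats = GenomicRanges::GRanges(),
                              exons = GenomicRanges::GRanges(),
                              introns = GenomicRanges::GRanges(),
                              genome_lengths = NULL) {
  structure(list(simple_repeats = simple_repeats, sines = sines, lines = lines,
                 other_repeats = other_repeats, exons = exons, introns = introns,
                 genome_lengths = genome_lengths),
            class = "annotation_tracks")
}

#' Load annotation tracks from BED / GTF files
#'
#' Splits RepeatMasker-style BED rows by the repeat class carried in the name
#' column (`SINE`, `LINE`, `Simple_repeat`, and the usual other classes;
#' strings outside the known vocabulary go to `other_repeats` with a
#' warning). Simple repeats come from their dedicated BED. Exons are taken
#' from GTF `exon` features; introns are derived as gene extent minus exons.
#'
#' @param rmsk_bed RepeatMasker-style BED file (name column = class, e.g.
#'   `SINE/Alu`); `NULL` for none.
#' @param simple_repeat_bed simple-repeat BED file; `NULL` for none.
#' @param gene_gtf GTF/GFF file with `exon` (and optionally `gene`)
#'   features; `NULL` for none.
#' @param genome_lengths named vector of chromosome lengths.
#' @return an `annotation_tracks` object (per-class ranges reduced/merged).
#' @export
load_tracks <- function(rmsk_bed = NULL, simple_repeat_bed = NULL, gene_gtf = NULL,
                        genome_lengths = NULL) {
  known_other <- c("LTR", "DNA", "Satellite", "Low_complexity", "Retroposon",
                   "RC", "rRNA", "tRNA", "snRNA", "srpRNA", "scRNA", "Unknown")
  sines <- lines <- other <- simple <- exons <- introns <- GenomicRanges::GRanges()
  if (!is.null(rmsk_bed)) {
    gr <- rtracklayer::import(rmsk_bed, format = "BED")
    cls <- sub("/.*$", "", gr$name)
    cls[is.na(cls)] <- "Unknown"
    unknown <- setdiff(unique(cls), c("SINE", "LINE", "Simple_repeat", known_other))
    if (length(unknown)) {
      warning("unknown repeat class(es) treated as other_repeat: ",
              paste(unknown, collapse = ", "))
    }
    sines <- GenomicRanges::reduce(gr[cls == "SINE"])
    lines <- GenomicRanges::reduce(gr[cls == "LINE"])
    simple <- GenomicRanges::reduce(gr[cls == "Simple_repeat"])
    other <- GenomicRanges::reduce(gr[!(cls %in% c("SINE", "LINE", "Simple_repeat"))])
  }
  if (!is.null(simple_repeat_bed)) {
    sr <- rtracklayer::import(simple_repeat_bed, format = "BED")
    simple <- GenomicRanges::reduce(c(GenomicRanges::granges(simple), GenomicRanges::granges(sr)))
  }
  if (!is.null(gene_gtf)) {
    gg <- rtracklayer::import(gene_gtf)
    ex <- gg[gg$type == "exon"]
    exons <- GenomicRanges::reduce(GenomicRanges::granges(ex))
    genes <- gg[gg$type == "gene"]
    gene_extent <- if (length(genes)) GenomicRanges::reduce(GenomicRanges::granges(genes))
      else GenomicRanges::reduce(GenomicRanges::granges(ex))
    introns <- GenomicRanges::setdiff(gene_extent, exons)
  }
  annotation_tracks(simple_repeats = simple, sines = sines, lines = lines,
                    other_repeats = other, exons = exons, introns = introns,
                    genome_lengths = genome_lengths)
}

.point_in <- function(chrom, pos, gr) {
  if (length(gr) == 0) return(rep(FALSE, length(pos)))
  pt <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(pt, gr) > 0
}

#' Classify one or more insertion sites against the tracks
#'
#' The context is decided by the single anchor-base point. Overlapping repeat
#' classes are resolved with priority simple repeat > SINE > LINE > other
#' repeat > non-repeated; the genic axis with exonic > intronic > intergenic.
#'
#' @param chrom chromosome name(s) (recycled).
#' @param pos position(s).
#' @param tracks an `annotation_tracks` object.
#' @return data.frame with factor columns `repeat_context` and
#'   `genic_context`.
#' @export
classify_site <- function(chrom, pos, tracks) {
  stopifnot(inherits(tracks, "annotation_tracks"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  if (!is.null(tracks$genome_lengths)) {
    bad <- !(chrom %in% names(tracks$genome_lengths))
    if (any(bad)) stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  }
  rep_ctx <- rep("non_repeated", n)
  rep_ctx[.point_in(chrom, pos, tracks$other_repeats)] <- "other_repeat"
  rep_ctx[.point_in(chrom, pos, tracks$lines)] <- "line"
  rep_ctx[.point_in(chrom, pos, tracks$sines)] <- "sine"
  rep_ctx[.point_in(chrom, pos, tracks$simple_repeats)] <- "simple_repeat"
  gen_ctx <- rep("intergenic", n)
  gen_ctx[.point_in(chrom, pos, tracks$introns)] <- "intronic"
  gen_ctx[.point_in(chrom, pos, tracks$exons)] <- "exonic"
  data.frame(repeat_context = factor(rep_ctx, levels = REPEAT_CLASSES),
             genic_context = factor(gen_ctx, levels = GENIC_CLASSES))
}

#' Fraction of the genome covered by a track class
#'
#' Merged-interval length of the class divided by the total genome length.
#'
#' @param tracks an `annotation_tracks` with `genome_lengths` set.
#' @param class one of `"simple_repeat"`, `"sine"`, `"line"`,
#'   `"other_repeat"`, `"exon"`, `"intron"`.
#' @return fraction in \[0, 1\].
#' @export
genome_fraction <- function(tracks, class = c("simple_repeat", "sine", "line",
                                              "other_repeat", "exon", "intron")) {
  stopifnot(inherits(tracks, "annotation_tracks"))
  class <- match.arg(class)
  if (is.null(tracks$genome_lengths)) stop("tracks lack genome_lengths")
  gr <- switch(class,
               simple_repeat = tracks$simple_repeats, sine = tracks$sines,
               line = tracks$lines, other_repeat = tracks$other_repeats,
               exon = tracks$exons, intron = tracks$introns)
  if (length(gr) == 0) return(0)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr)))) /
    sum(as.numeric(tracks$genome_lengths))
}
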