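# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom methods is
.as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- "chr1"
    return(g)
  }
  if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(genome)
    if (is.null(names(genome))) names(g) <- paste0("chr", seq_along(g)) else names(g) <- names(genome)
    return(g)
  }
  stop("genome must be a DNAStringSet, DNAString or named character vector")
}

# Extract one chromosome as a plain character string. Accepts a named
# character vector directly (fast path used by per-record loops, which
# pre-convert the genome once with .genome_chars()).
.chrom_seq <- function(genome, chrom) {
  if (is.character(genome) && !is.null(names(genome))) {
    if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' absent from genome")
    return(genome[[chrom]])
  }
  genome <- .as_genome(genome)
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' absent from genome")
  }
  as.character(genome[[chrom]])
}

# One-off conversion of a genome to a named character vector.
.genome_chars <- function(genome) {
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  genome <- .as_genome(genome)
  stats::setNames(as.character(genome), names(genome))
}

# Random DNA string of length n (uses the current RNG stream).
.rand_dna <- function(n, bases = DNA_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Substitute approximately `rate` of positions with a different base.
.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  idx <- sample.int(n, k)
  for (i in idx) {
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Merge 1-based closed intervals, bridging gaps of at most `gap` bases.
# Returns a data.frame(start, end) sorted by start.
.merge_intervals <- function(start, end, gap = 0) {
  if (length(start) == 0) return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + gap + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# Longest merged-segment length over a set of intervals (gap-bridged), clipped
# to [1, len]. Used for the "longest contiguous annotated segment" coverages.
.longest_segment <- function(start, end, len, gap = 10) {
  if (length(start) == 0) return(0L)
  start <- pmax(1L, as.integer(start)); end <- pmin(as.integer(len), as.integer(end))
  keep <- end >= start
  if (!any(keep)) return(0L)
  m <- .merge_intervals(start[keep], end[keep], gap = gap)
  max(m$end - m$start + 1L)
}

# Total covered length (union, no gap bridging), clipped to [1, len].
.union_coverage <- function(start, end, len) {
  if (length(start) == 0) return(0L)
  start <- pmax(1L, as.integer(start)); end <- pmin(as.integer(len), as.integer(end))
  keep <- end >= start
  if (!any(keep)) return(0L)
  m <- .merge_intervals(start[keep], end[keep], gap = 0)
  sum(m$end - m$start + 1L)
}

# Parse a semicolon-separated VCF INFO string into a named character vector.
# Flag entries (no '=') get value "TRUE".
.parse_info <- function(info) {
  if (is.na(info) || info == "." || info == "") return(character(0))
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", parts, fixed = TRUE)
  keys <- ifelse(has_eq, sub("=.*$", "", parts), parts)
  vals <- ifelse(has_eq, sub("^[^=]*=", "", parts), "TRUE")
  stats::setNames(vals, keys)
}

# Vectorised INFO tag lookup over a character vector of INFO strings.
.info_tag <- function(info, key) {
  vapply(info, function(x) {
    tags <- .parse_info(x)
    if (key %in% names(tags)) unname(tags[[key]]) else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

.empty_records <- function() {
  data.frame(
    record_id = character(0), chrom = character(0), pos = integer(0),
    inserted_seq = character(0), size = integer(0), filter = character(0),
    info = character(0), genotype = character(0), resolved = logical(0),
    stringsAsFactors = FALSE
  )
}
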