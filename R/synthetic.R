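# Download-free stand-ins for the external inputs: a random annotated genome
# with planted genes, simple repeats and SINE/LINE-like mobile elements, a
# consensus library for those elements, donor pools of novel sequence, and
# labeled insertion callsets whose records are built to satisfy exactly one
# insertion sub-type definition.

#' Synthetic genome configuration
#'
#' @param length genome length in bp.
#' @param n_genes number of planted two-exon genes (each contributes two
#'   exons and one intron).
#' @param n_simple_repeats number of planted tandem arrays; half are shorter
#'   than 300 bp, half longer.
#' @param n_sines,n_lines number of planted mobile-element instances per
#'   family kind.
#' @param n_sine_families,n_line_families consensus library shape.
#' @param sine_len,line_len consensus lengths (SINE-scale ~300 bp,
#'   LINE-scale ~6 kb; genomic LINE instances are 5' truncated).
#' @param divergence substitution divergence of planted element copies from
#'   their consensus (default 0.05, within the 10% the identity rules
#'   tolerate).
#' @param gc GC content of the random background.
#' @param min_gap minimal gap between planted features.
#' @param seed RNG seed.
#' @export
synthetic_genome_config <- function(length = 1e6, n_genes = 60, n_simple_repeats = 40,
                                    n_sines = 25, n_lines = 3,
                                    n_sine_families = 2, n_line_families = 1,
                                    sine_len = 300, line_len = 6000,
                                    divergence = 0.05, gc = 0.41,
                                    min_gap = 200, seed = 1) {
  as.list(environment())
}

.rand_dna_gc <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic annotated genome
#'
#' Builds a uniform-random background genome and plants non-overlapping
#' features: two-exon genes (annotation only), genuine tandem arrays
#' (detectable by [find_tandem_structure()]), and mobile-element instances
#' that are mutated copies of library consensus sequences (so they align to
#' their consensus at >= 90% identity). Deterministic given the config seed.
#'
#' @param cfg a [synthetic_genome_config()].
#' @return list with `genome` (named character, single chromosome `chr1`),
#'   `tracks` ([annotation_tracks()]), `me_library` (named character of
#'   consensus sequences) and `features` (data.frame of planted intervals).
#' @export
generate_genome <- function(cfg = synthetic_genome_config()) {
  set.seed(cfg$seed)
  L <- as.integer(cfg$length)

  me_library <- c(
    stats::setNames(lapply(seq_len(cfg$n_sine_families), function(i) .rand_dna_gc(cfg$sine_len, cfg$gc)),
                    paste0("SINE", seq_len(cfg$n_sine_families))),
    stats::setNames(lapply(seq_len(cfg$n_line_families), function(i) .rand_dna_gc(cfg$line_len, cfg$gc)),
                    paste0("LINE", seq_len(cfg$n_line_families)))
  )
  me_library <- vapply(me_library, identity, character(1))

  feats <- list()
  add <- function(kind, seq, meta = NA_character_) {
    feats[[length(feats) + 1L]] <<- list(kind = kind, seq = seq, meta = meta)
  }
  for (i in seq_len(cfg$n_genes)) {
    e1 <- .rand_dna_gc(sample(300:800, 1), cfg$gc)
    intr <- .rand_dna_gc(sample(500:1500, 1), cfg$gc)
    e2 <- .rand_dna_gc(sample(300:800, 1), cfg$gc)
    add("gene", paste0(e1, intr, e2),
        meta = paste(nchar(e1), nchar(intr), nchar(e2), sep = ","))
  }
  for (i in seq_len(cfg$n_simple_repeats)) {
    seed_size <- sample(2:25, 1)
    motif <- .rand_dna(seed_size)
    target_len <- if (i %% 2 == 0) sample(80:250, 1) else sample(350:800, 1)
    arr <- strtrim(strrep(motif, ceiling(target_len / seed_size)), target_len)
    add("simple_repeat", arr, meta = as.character(seed_size))
  }
  sine_fams <- grep("^SINE", names(me_library), value = TRUE)
  for (i in seq_len(cfg$n_sines)) {
    fam <- sample(sine_fams, 1)
    add("sine", .mutate_seq(me_library[[fam]], cfg$divergence), meta = fam)
  }
  line_fams <- grep("^LINE", names(me_library), value = TRUE)
  for (i in seq_len(cfg$n_lines)) {
    fam <- sample(line_fams, 1)
    trunc_len <- sample(500:3000, 1)
    cons <- me_library[[fam]]
    piece <- substr(cons, nchar(cons) - trunc_len + 1L, nchar(cons))  # 5' truncation
    add("line", .mutate_seq(piece, cfg$divergence), meta = fam)
  }

  feat_lens <- vapply(feats, function(f) nchar(f$seq), integer(1))
  nf <- length(feats)
  free <- L - sum(feat_lens)
  if (free < cfg$min_gap * (nf + 1L)) {
    stop("unsatisfiable packing: features + minimal gaps exceed genome length")
  }
  ord <- sample.int(nf)
  extra <- as.vector(stats::rmultinom(1, free - cfg$min_gap * (nf + 1L), rep(1, nf + 1L)))
  gaps <- cfg$min_gap + extra

  pieces <- character(2L * nf + 1L)
  rows <- vector("list", nf)
  cursor <- 0L
  for (k in seq_len(nf)) {
    g <- .rand_dna_gc(gaps[k], cfg$gc)
    pieces[2L * k - 1L] <- g
    cursor <- cursor + gaps[k]
    f <- feats[[ord[k]]]
    start <- cursor + 1L
    end <- cursor + nchar(f$seq)
    pieces[2L * k] <- f$seq
    cursor <- end
    rows[[k]] <- data.frame(kind = f$kind, start = start, end = end,
                            meta = f$meta, stringsAsFactors = FALSE)
  }
  pieces[2L * nf + 1L] <- .rand_dna_gc(gaps[nf + 1L], cfg$gc)
  genome <- stats::setNames(paste(pieces, collapse = ""), "chr1")
  stopifnot(nchar(genome) == L)
  features <- do.call(rbind, rows)
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL

  gr_of <- function(kind) {
    f <- features[features$kind == kind, , drop = FALSE]
    if (!nrow(f)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges("chr1", IRanges::IRanges(f$start, f$end))
  }
  gn <- features[features$kind == "gene", , drop = FALSE]
  ex_s <- integer(0); ex_e <- integer(0); in_s <- integer(0); in_e <- integer(0)
  for (i in seq_len(nrow(gn))) {
    ln <- as.integer(strsplit(gn$meta[i], ",", fixed = TRUE)[[1]])
    s <- gn$start[i]
    ex_s <- c(ex_s, s, s + ln[1] + ln[2]); ex_e <- c(ex_e, s + ln[1] - 1L, gn$end[i])
    in_s <- c(in_s, s + ln[1]); in_e <- c(in_e, s + ln[1] + ln[2] - 1L)
  }
  mk_gr <- function(s, e) {
    if (!length(s)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  }
  tracks <- annotation_tracks(
    simple_repeats = gr_of("simple_repeat"),
    sines = gr_of("sine"), lines = gr_of("line"),
    other_repeats = GenomicRanges::GRanges(),
    exons = mk_gr(ex_s, ex_e),
    introns = mk_gr(in_s, in_e),
    genome_lengths = c(chr1 = L))

  list(genome = genome, tracks = tracks, me_library = me_library, features = features)
}

#' Donor pool of novel sequences
#'
#' Random sequences standing in for exonic donor material foreign to the
#' genome (the role played by yeast exons in chromosome-scale simulations):
#' at 250 bp a uniform-random sequence is novel with overwhelming
#' probability.
#'
#' @param n number of donors.
#' @param len donor length (take prefixes for shorter insertions).
#' @param gc GC content.
#' @param seed optional RNG seed.
#' @return named character vector `donor1..donorn`.
#' @export
donor_pool <- function(n = 300, len = 1200, gc = 0.41, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(vapply(seq_len(n), function(i) .rand_dna_gc(len, gc), character(1)),
                  paste0("donor", seq_len(n)))
}

# Sample n sites inside the given GRanges intervals, pairwise at least
# min_dist apart, at least `edge` away from chromosome ends.
.sample_sites_in <- function(gr, genome_lengths, n, min_dist = 60L, edge = 500L,
                             max_tries = 50L) {
  if (length(gr) == 0) stop("no eligible intervals for site sampling")
  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  w <- ends - starts + 1L
  pos <- integer(0); chr <- character(0)
  tries <- 0L
  while (length(pos) < n) {
    tries <- tries + 1L
    if (tries > max_tries * n) {
      stop("insufficient eligible sites: needed ", n, ", placed ", length(pos))
    }
    i <- sample.int(length(gr), 1, prob = w)
    p <- starts[i] + sample.int(w[i], 1) - 1L
    lg <- genome_lengths[[chroms[i]]]
    if (p <= edge || p >= lg - edge) next
    same <- chr == chroms[i]
    if (any(same) && min(abs(pos[same] - p)) < min_dist) next
    pos <- c(pos, p); chr <- c(chr, chroms[i])
  }
  o <- order(chr, pos)
  data.frame(chrom = chr[o], pos = pos[o], stringsAsFactors = FALSE)
}

# Complement of all planted features (background) as GRanges.
.background_ranges <- function(gen, margin = 300L) {
  L <- gen$tracks$genome_lengths
  all_feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(gen$features$start - margin,
                             gen$features$end + margin))
  GenomicRanges::setdiff(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, L[["chr1"]])),
    GenomicRanges::reduce(all_feats))
}

# Junction hygiene: force a mismatch between the insertion extremity and the
# adjacent reference base so designed junctional homology is exact.
.force_mismatch <- function(ins, at, ref_base) {
  if (at < 1 || at > nchar(ins)) return(ins)
  cur <- substr(ins, at, at)
  if (cur != ref_base) return(ins)
  substr(ins, at, at) <- sample(setdiff(DNA_BASES, ref_base), 1)
  ins
}

#' Labeled callset configuration
#'
#' @param n number of records.
#' @param type_mix named fractions over the five insertion types (must sum
#'   to 1).
#' @param size named numeric: insertion size in bp per type (mobile elements
#'   use the consensus-copy length regardless).
#' @param homology designed junctional homology in bp planted at the right
#'   junction (0 = none).
#' @param context one of the repeat classes to place sites in, or
#'   `"non_repeated"` for background sites.
#' @param seed RNG seed.
#' @export
labeled_callset_config <- function(n = 100,
                                   type_mix = c(tandem_repeat = 0.2, mobile_element = 0.2,
                                                tandem_duplication = 0.2,
                                                dispersed_duplication = 0.2,
                                                novel_sequence = 0.2),
                                   size = 250L, homology = 0L,
                                   context = "non_repeated", seed = 1) {
  stopifnot(abs(sum(type_mix) - 1) < 1e-8,
            all(names(type_mix) %in% INSERTION_TYPES))
  as.list(environment())
}

#' Generate a labeled insertion callset on a synthetic genome
#'
#' Each record's inserted sequence is constructed to satisfy exactly one
#' sub-type definition: a tandem array of a short random motif, a mutated
#' copy of a mobile-element consensus, a copy of the right-flank sequence
#' (tandem duplication), a copy of a distant unique background segment
#' (dispersed duplication, copy count 1), or uniform-random novel sequence.
#' Sites are placed in the requested context; designed junctional homology
#' is planted at the right junction with a forced mismatch immediately
#' beyond it, and junction-adjacent mismatches are forced when the design
#' asks for zero homology.
#'
#' @param gen a [generate_genome()] result.
#' @param cfg a [labeled_callset_config()].
#' @return list with `callset` (an `inschar_callset`) and `truth`
#'   (data.frame of designed labels: `record_id`, `type`,
#'   `designed_homology`, `context`, `size`).
#' @export
generate_labeled_callset <- function(gen, cfg = labeled_callset_config()) {
  set.seed(cfg$seed)
  g <- gen$genome[["chr1"]]
  lg <- nchar(g)
  n <- cfg$n
  if (n == 0) {
    return(list(callset = callset(convention = "generic", source_label = "synthetic"),
                truth = data.frame(record_id = character(0), type = character(0),
                                   designed_homology = integer(0), context = character(0),
                                   size = integer(0), stringsAsFactors = FALSE)))
  }
  types <- sample(names(cfg$type_mix), n, replace = TRUE, prob = cfg$type_mix)
  site_gr <- switch(cfg$context,
                    non_repeated = .background_ranges(gen),
                    simple_repeat = gen$tracks$simple_repeats,
                    sine = gen$tracks$sines, line = gen$tracks$lines,
                    stop("unknown context class: ", cfg$context))
  sites <- .sample_sites_in(site_gr, gen$tracks$genome_lengths, n,
                            min_dist = 700L)
  # donor loci for dispersed duplications: distant unique background segments
  bg <- .background_ranges(gen, margin = 400L)
  rec <- list(); truth <- list()
  for (i in seq_len(n)) {
    pos <- sites$pos[i]
    size <- as.integer(cfg$size)
    ty <- types[i]
    if (ty == "tandem_repeat") {
      motif <- .rand_dna(sample(3:10, 1))
      ins <- strtrim(strrep(motif, ceiling(size / nchar(motif))), size)
    } else if (ty == "mobile_element") {
      fam <- sample(names(gen$me_library), 1)
      cons <- gen$me_library[[fam]]
      size <- min(nchar(cons), max(250L, size))
      ins <- .mutate_seq(substr(cons, 1L, size), 0.05)
    } else if (ty == "tandem_duplication") {
      ins <- substr(g, pos + 1L, pos + size)
    } else if (ty == "dispersed_duplication") {
      repeat {
        donor <- .sample_sites_in(bg, gen$tracks$genome_lengths, 1, min_dist = 1L)
        if (abs(donor$pos[1] - pos) > 2L * size + 1000L) break
      }
      ins <- substr(g, donor$pos[1], donor$pos[1] + size - 1L)
    } else {
      ins <- .rand_dna(size)
    }
    hom <- as.integer(cfg$homology)
    if (hom > 0L) {
      # verify the design with the detector and resample the tail if the
      # alignment rule extends past the planted homology by chance
      for (try in 1:25) {
        substr(ins, 1L, hom) <- substr(g, pos + 1L, pos + hom)
        ins <- .force_mismatch(ins, hom + 1L, substr(g, pos + hom + 1L, pos + hom + 1L))
        ins <- .force_mismatch(ins, nchar(ins), substr(g, pos, pos))
        h <- junctional_homology_size(sites$chrom[i], pos, ins, gen$genome)
        if (h$right_size == hom && h$total_size == hom) break
        ins <- paste0(substr(ins, 1L, hom), .rand_dna(nchar(ins) - hom))
      }
    } else if (ty %in% c("novel_sequence", "mobile_element", "dispersed_duplication")) {
      ins <- .force_mismatch(ins, 1L, substr(g, pos + 1L, pos + 1L))
      ins <- .force_mismatch(ins, nchar(ins), substr(g, pos, pos))
    }
    rid <- sprintf("synth%04d", i)
    rec[[i]] <- data.frame(record_id = rid, chrom = sites$chrom[i], pos = pos,
                           inserted_seq = ins, size = nchar(ins), filter = "PASS",
                           info = paste0("TYPE=", ty), genotype = "1/1",
                           resolved = TRUE, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(record_id = rid, type = ty, designed_homology = hom,
                             context = cfg$context, size = nchar(ins),
                             stringsAsFactors = FALSE)
  }
  cs <- callset(do.call(rbind, rec), convention = "generic", source_label = "synthetic")
  list(callset = cs, truth = do.call(rbind, truth))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
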