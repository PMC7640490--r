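# Scenario-structured insertion simulation: a baseline of novel exonic
# insertions plus four families of single-factor deviations (size, type,
# junctional homology, genomic context) and three real-callset replays,
# emitted as truth tables, mutated genome sequences and truth VCFs.

SCENARIO_SIZES <- c(50L, 500L, 1000L)
SCENARIO_TYPES <- c("dispersed_dup", "tr_seed6", "tr_seed25", "tandem_dup", "mobile_element")
SCENARIO_HOMOLOGIES <- c(10L, 20L, 50L, 100L, 150L)
SCENARIO_CONTEXTS <- c("sine", "line", "simple_repeat_small", "simple_repeat_large", "proximal")
SCENARIO_REAL <- c("novel_at_real_sites", "real_in_exons", "real_at_real_sites")

#' Enumerate the default simulation suite
#'
#' One baseline, three insertion sizes, five insertion types, five
#' junctional-homology sizes, five genomic contexts and three real-callset
#' replays: 22 datasets of `n_insertions` insertions each, in deterministic
#' order. The non-repeated context dataset is the baseline itself (exons are
#' non-repeated), which is what keeps the suite at 22 rather than 23.
#'
#' @param n_insertions insertions per dataset (default 200).
#' @param scenarios restrict to a subset of
#'   `c("baseline","size","type","homology","context","real")`.
#' @return data.frame with columns `scenario`, `parameter`, `n_insertions`.
#' @export
build_scenario_suite <- function(n_insertions = 200,
                                 scenarios = c("baseline", "size", "type",
                                               "homology", "context", "real")) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  rows <- list()
  if ("baseline" %in% scenarios) rows[[length(rows) + 1]] <- c("baseline", "baseline")
  if ("size" %in% scenarios) for (s in SCENARIO_SIZES) rows[[length(rows) + 1]] <- c("size", s)
  if ("type" %in% scenarios) for (t in SCENARIO_TYPES) rows[[length(rows) + 1]] <- c("type", t)
  if ("homology" %in% scenarios) for (h in SCENARIO_HOMOLOGIES) rows[[length(rows) + 1]] <- c("homology", h)
  if ("context" %in% scenarios) for (cx in SCENARIO_CONTEXTS) rows[[length(rows) + 1]] <- c("context", cx)
  if ("real" %in% scenarios) for (r in SCENARIO_REAL) rows[[length(rows) + 1]] <- c("real", r)
  out <- data.frame(scenario = vapply(rows, `[`, "", 1),
                    parameter = vapply(rows, `[`, "", 2),
                    n_insertions = n_insertions, stringsAsFactors = FALSE)
  out
}

# Baseline insertion sites: n exonic positions, deterministic given site_seed.
.baseline_sites <- function(gen, n, site_seed) {
  set.seed(site_seed)
  .sample_sites_in(gen$tracks$exons, gen$tracks$genome_lengths, n,
                   min_dist = 60L, edge = 1100L)
}

.trim_or_stop <- function(seq, len, what) {
  if (nchar(seq) < len) stop(what, " shorter than requested size ", len)
  strtrim(seq, len)
}

#' Generate the truth set for one simulation scenario
#'
#' Baseline: `n` novel 250 bp donor sequences at exonic sites with zero
#' junctional homology (junction-adjacent mismatches forced). Size scenarios
#' keep the baseline locations and use donor sequences of the requested
#' size. Type scenarios replace the inserted sequences: tandem repeats tile
#' a 6 or 25 bp seed taken from the left breakpoint junction, tandem
#' duplications duplicate the 250 bp right breakpoint sequence, mobile
#' elements are 200-300 bp pieces of annotated elements, dispersed
#' duplications are exonic segments of the same chromosome. Homology
#' scenarios replace the first X bases of each baseline insertion with the
#' right breakpoint sequence (mismatch forced at X+1). Context scenarios
#' place baseline-style insertions inside the requested track class, or
#' simulate proximal pairs separated by a 5-150 bp gap. Real scenarios
#' replay a supplied truth table.
#'
#' @param scenario,parameter a row of [build_scenario_suite()].
#' @param gen a [generate_genome()] result (genome + tracks + ME library).
#' @param donors donor pool from [donor_pool()]; donors must be at least as
#'   long as the requested insertion size.
#' @param n number of insertions (default 200).
#' @param seed RNG seed for this dataset.
#' @param site_seed seed fixing the baseline locations shared across
#'   scenarios (default 97).
#' @param real_truth truth data.frame required by the `real` scenarios
#'   (columns `chrom`, `pos`, `inserted_seq`).
#' @return truth data.frame: `record_id`, `chrom`, `pos`, `inserted_seq`,
#'   `size`, `type`, `expected_homology`, `context`, `scenario`, `parameter`;
#'   sorted by position, positions unique.
#' @export
generate_insertions <- function(scenario, parameter, gen, donors, n = 200,
                                seed = 1, site_seed = 97, real_truth = NULL) {
  g <- gen$genome[["chr1"]]
  lg <- nchar(g)
  base_len <- 250L

  mk_truth <- function(chrom, pos, ins, type, exphom, context) {
    o <- order(chrom, pos)
    data.frame(record_id = sprintf("sim%04d", seq_along(pos)),
               chrom = chrom[o], pos = pos[o], inserted_seq = ins[o],
               size = nchar(ins[o]), type = type[o],
               expected_homology = exphom[o], context = context[o],
               scenario = scenario, parameter = as.character(parameter),
               stringsAsFactors = FALSE)
  }
  hygiene <- function(ins, pos) {
    ins <- .force_mismatch(ins, 1L, substr(g, pos + 1L, pos + 1L))
    .force_mismatch(ins, nchar(ins), substr(g, pos, pos))
  }
  novel_at <- function(sites, len) {
    set.seed(seed)
    idx <- sample(seq_along(donors), nrow(sites), replace = length(donors) < nrow(sites))
    ins <- vapply(seq_len(nrow(sites)), function(i) {
      hygiene(.trim_or_stop(donors[[idx[i]]], len, "donor"), sites$pos[i])
    }, character(1))
    ins
  }

  if (scenario == "baseline" || (scenario == "context" && identical(parameter, "non_repeated"))) {
    sites <- .baseline_sites(gen, n, site_seed)
    ins <- novel_at(sites, base_len)
    return(mk_truth(sites$chrom, sites$pos, ins, rep("novel_sequence", n),
                    rep(0L, n), rep("exonic", n)))
  }
  if (scenario == "size") {
    len <- as.integer(parameter)
    sites <- .baseline_sites(gen, n, site_seed)
    ins <- novel_at(sites, len)
    return(mk_truth(sites$chrom, sites$pos, ins, rep("novel_sequence", n),
                    rep(0L, n), rep("exonic", n)))
  }
  if (scenario == "type") {
    sites <- .baseline_sites(gen, n, site_seed)
    set.seed(seed)
    ins <- character(n)
    for (i in seq_len(n)) {
      pos <- sites$pos[i]
      if (parameter %in% c("tr_seed6", "tr_seed25")) {
        p <- if (parameter == "tr_seed6") 6L else 25L
        motif <- substr(g, pos - p + 1L, pos)  # seed from the left breakpoint junction
        ins[i] <- strtrim(strrep(motif, ceiling(base_len / p)), base_len)
      } else if (parameter == "tandem_dup") {
        ins[i] <- substr(g, pos + 1L, pos + base_len)
      } else if (parameter == "mobile_element") {
        inst <- gen$tracks$sines
        if (length(inst) == 0) stop("no annotated mobile elements to draw from")
        j <- sample.int(length(inst), 1)
        len <- sample(200:300, 1)
        s0 <- GenomicRanges::start(inst)[j]
        len <- min(len, GenomicRanges::end(inst)[j] - s0 + 1L)
        ins[i] <- substr(g, s0, s0 + len - 1L)
      } else if (parameter == "dispersed_dup") {
        ex <- gen$tracks$exons
        w <- GenomicRanges::width(ex)
        elig <- which(w >= base_len)
        repeat {
          j <- sample(elig, 1)
          s0 <- GenomicRanges::start(ex)[j] +
            sample.int(w[j] - base_len + 1L, 1) - 1L
          if (abs(s0 - pos) > 2000L) break
        }
        ins[i] <- substr(g, s0, s0 + base_len - 1L)
      } else stop("unknown type parameter: ", parameter)
      if (parameter %in% c("mobile_element", "dispersed_dup")) {
        ins[i] <- hygiene(ins[i], pos)
      }
    }
    type_label <- c(dispersed_dup = "dispersed_duplication", tr_seed6 = "tandem_repeat",
                    tr_seed25 = "tandem_repeat", tandem_dup = "tandem_duplication",
                    mobile_element = "mobile_element")[[parameter]]
    exphom <- if (parameter == "tandem_dup") rep(base_len, n) else rep(NA_integer_, n)
    return(mk_truth(sites$chrom, sites$pos, ins, rep(type_label, n), exphom,
                    rep("exonic", n)))
  }
  if (scenario == "homology") {
    X <- as.integer(parameter)
    sites <- .baseline_sites(gen, n, site_seed)
    ins <- novel_at(sites, base_len)
    for (i in seq_len(n)) {
      pos <- sites$pos[i]
      # plant the homology, then verify with the detector itself: the 90%
      # identity alignment rule can legitimately extend past a single
      # mismatch, so resample the insertion tail until the design is exact
      for (try in 1:25) {
        substr(ins[i], 1L, X) <- substr(g, pos + 1L, pos + X)
        ins[i] <- .force_mismatch(ins[i], X + 1L, substr(g, pos + X + 1L, pos + X + 1L))
        ins[i] <- .force_mismatch(ins[i], base_len, substr(g, pos, pos))
        h <- junctional_homology_size(sites$chrom[i], pos, ins[i], gen$genome)
        if (h$right_size == X && h$left_size == 0L && h$total_size == X) break
        ins[i] <- paste0(substr(ins[i], 1L, X), .rand_dna(base_len - X))
      }
    }
    return(mk_truth(sites$chrom, sites$pos, ins, rep("novel_sequence", n),
                    rep(X, n), rep("exonic", n)))
  }
  if (scenario == "context") {
    set.seed(seed)
    if (parameter == "proximal") {
      n1 <- n %/% 2L
      sites <- .baseline_sites(gen, n1, site_seed)
      ins1 <- novel_at(sites, base_len)
      gap <- sample(5:150, n1, replace = TRUE)
      pos2 <- sites$pos + gap
      set.seed(seed + 1L)
      idx <- sample(seq_along(donors), n1, replace = length(donors) < n1)
      ins2 <- vapply(seq_len(n1), function(i) {
        hygiene(.trim_or_stop(donors[[idx[i]]], base_len, "donor"), pos2[i])
      }, character(1))
      chrom <- c(sites$chrom, sites$chrom)
      pos <- c(sites$pos, pos2)
      ins <- c(ins1, ins2)
      keep <- !duplicated(paste(chrom, pos))
      return(mk_truth(chrom[keep], pos[keep], ins[keep],
                      rep("novel_sequence", sum(keep)), rep(0L, sum(keep)),
                      rep("proximal", sum(keep))))
    }
    gr <- switch(parameter,
                 sine = gen$tracks$sines, line = gen$tracks$lines,
                 simple_repeat_small = {
                   sr <- gen$tracks$simple_repeats
                   sr[GenomicRanges::width(sr) < 300]
                 },
                 simple_repeat_large = {
                   sr <- gen$tracks$simple_repeats
                   sr[GenomicRanges::width(sr) > 300]
                 },
                 stop("unknown context parameter: ", parameter))
    sites <- .sample_sites_in(gr, gen$tracks$genome_lengths, n, min_dist = 25L,
                              edge = 1100L)
    ins <- novel_at(sites, base_len)
    return(mk_truth(sites$chrom, sites$pos, ins, rep("novel_sequence", n),
                    rep(NA_integer_, n), rep(parameter, n)))
  }
  if (scenario == "real") {
    if (is.null(real_truth)) stop("real scenarios require a real_truth table")
    rt <- real_truth[order(real_truth$chrom, real_truth$pos), , drop = FALSE]
    if (parameter == "real_at_real_sites") {
      return(mk_truth(rt$chrom, rt$pos, rt$inserted_seq,
                      rep("real", nrow(rt)), rep(NA_integer_, nrow(rt)),
                      rep("real", nrow(rt))))
    }
    if (parameter == "novel_at_real_sites") {
      sites <- data.frame(chrom = rt$chrom, pos = rt$pos, stringsAsFactors = FALSE)
      ins <- novel_at(sites, base_len)
      return(mk_truth(sites$chrom, sites$pos, ins,
                      rep("novel_sequence", nrow(rt)), rep(0L, nrow(rt)),
                      rep("real_sites", nrow(rt))))
    }
    if (parameter == "real_in_exons") {
      sites <- .baseline_sites(gen, nrow(rt), site_seed)
      return(mk_truth(sites$chrom, sites$pos, rt$inserted_seq,
                      rep("real", nrow(rt)), rep(NA_integer_, nrow(rt)),
                      rep("exonic", nrow(rt))))
    }
    stop("unknown real parameter: ", parameter)
  }
  stop("unknown scenario: ", scenario)
}

#' Apply a truth set of insertions to a genome
#'
#' Splices every inserted sequence in after its anchor base, applying
#' insertions in descending coordinate order per chromosome so earlier
#' splices do not shift later coordinates. Output length equals input length
#' plus the summed insertion sizes.
#'
#' @param genome genome (named character or `DNAStringSet`).
#' @param truth truth data.frame (`chrom`, `pos`, `inserted_seq`).
#' @return named character vector of mutated chromosome sequences.
#' @export
apply_insertions <- function(genome, truth) {
  genome <- .genome_chars(genome)
  if (anyDuplicated(paste(truth$chrom, truth$pos))) {
    stop("overlapping-position collision: two insertions share an anchor position")
  }
  out <- genome
  for (chrom in unique(truth$chrom)) {
    t <- truth[truth$chrom == chrom, , drop = FALSE]
    t <- t[order(-t$pos), , drop = FALSE]
    s <- out[[chrom]]
    for (i in seq_len(nrow(t))) {
      if (t$pos[i] < 1 || t$pos[i] > nchar(genome[[chrom]])) {
        stop("truth position outside chromosome: ", chrom, ":", t$pos[i])
      }
      s <- paste0(substr(s, 1L, t$pos[i]), t$inserted_seq[i],
                  substr(s, t$pos[i] + 1L, nchar(s)))
    }
    out[[chrom]] <- s
  }
  out
}

#' Write a truth set as a homozygous-insertion VCF
#'
#' One record per insertion: POS is the anchor base, REF the anchor base
#' from the genome, ALT is REF plus the inserted sequence, genotype `1/1`,
#' with the scenario labels carried in INFO. Reading the file back with
#' [read_vcf_insertions()] reproduces the truth set.
#'
#' @param truth truth data.frame from [generate_insertions()].
#' @param genome genome.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, genome, path) {
  info <- vapply(seq_len(nrow(truth)), function(i) {
    parts <- c(paste0("SVTYPE=INS"))
    if ("scenario" %in% names(truth)) parts <- c(parts, paste0("SCENARIO=", truth$scenario[i]),
                                                 paste0("PARAM=", truth$parameter[i]))
    if ("type" %in% names(truth)) parts <- c(parts, paste0("TYPE=", truth$type[i]))
    if ("expected_homology" %in% names(truth) && !is.na(truth$expected_homology[i])) {
      parts <- c(parts, paste0("EXPHOM=", truth$expected_homology[i]))
    }
    if ("context" %in% names(truth)) parts <- c(parts, paste0("CONTEXT=", truth$context[i]))
    paste(parts, collapse = ";")
  }, character(1))
  rec <- data.frame(record_id = truth$record_id, chrom = truth$chrom, pos = truth$pos,
                    inserted_seq = truth$inserted_seq, size = nchar(truth$inserted_seq),
                    filter = "PASS", info = info, genotype = "1/1", resolved = TRUE,
                    stringsAsFactors = FALSE)
  write_vcf(callset(rec, convention = "generic", source_label = "truth"),
            path, genome = genome)
}

#' Truth set as a callset (for self-consistency evaluation)
#'
#' @param truth truth data.frame.
#' @return an `inschar_callset` with FILTER `PASS` and genotype `1/1`.
#' @export
truth_as_callset <- function(truth) {
  rec <- data.frame(record_id = truth$record_id, chrom = truth$chrom, pos = truth$pos,
                    inserted_seq = truth$inserted_seq, size = nchar(truth$inserted_seq),
                    filter = "PASS", info = ".", genotype = "1/1", resolved = TRUE,
                    stringsAsFactors = FALSE)
  callset(rec, convention = "generic", source_label = "truth")
}
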