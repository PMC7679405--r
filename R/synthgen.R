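#' Specification for a synthetic annotated genome
#'
#' Describes the feature universe the generator forges: gene models with
#' UTRs/CDS-exons/introns, transposable-element families of the LTR and LINE
#' classes, satellite loci, and ncRNA blacklist loci (tRNA/rRNA/snRNA/snoRNA).
#' Every genomic k-mer of length `uniqueness_k` is made unique genome-wide
#' (up to reverse complement), so exact mapping of reads at least that long
#' is unambiguous by construction.
#'
#' @param n_genes number of protein-coding gene models.
#' @param exons_per_gene CDS-exons per gene (introns between them).
#' @param utr5_len,utr3_len,exon_len,intron_len part lengths in nt.
#' @param n_te_families number of transposon families.
#' @param te_class_mix proportions over classes `c(LTR=, LINE=)`; sums to 1.
#' @param te_len_range copy length interval in nt.
#' @param te_copies_per_family copies per family (alternating strands, so
#'   both orientations are represented).
#' @param satellite_unit length of one satellite locus in nt.
#' @param satellite_copies number of satellite loci.
#' @param n_blacklist_loci loci per blacklist class (tRNA, rRNA, snRNA,
#'   snoRNA).
#' @param blacklist_len blacklist locus length in nt.
#' @param uniqueness_k k-mer size whose genome-wide uniqueness is enforced.
#' @param n_contigs number of contigs the features are distributed over.
#' @param spacer_len random spacer between feature blocks, nt.
#' @param seed RNG seed.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 24, exons_per_gene = 3,
                        utr5_len = 120, utr3_len = 150,
                        exon_len = 200, intron_len = 150,
                        n_te_families = 8,
                        te_class_mix = c(LTR = 0.5, LINE = 0.5),
                        te_len_range = c(600, 1000),
                        te_copies_per_family = 4,
                        satellite_unit = 180, satellite_copies = 6,
                        n_blacklist_loci = 4, blacklist_len = 80,
                        uniqueness_k = 18, n_contigs = 2, spacer_len = 60,
                        seed = 1L) {
  check_proportions(te_class_mix[c("LTR", "LINE")], "te_class_mix")
  lens <- c(utr5_len, utr3_len, exon_len, intron_len,
            te_len_range, satellite_unit, blacklist_len)
  if (any(lens < uniqueness_k)) {
    stop("all feature lengths must be >= uniqueness_k", call. = FALSE)
  }
  stopifnot(n_genes >= 0, exons_per_gene >= 1, n_te_families >= 0,
            te_copies_per_family >= 1, satellite_copies >= 0,
            n_blacklist_loci >= 0, uniqueness_k >= 8, n_contigs >= 1,
            te_len_range[1] <= te_len_range[2])
  structure(list(
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
    exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
    n_te_families = as.integer(n_te_families),
    te_class_mix = te_class_mix[c("LTR", "LINE")],
    te_len_range = as.integer(te_len_range),
    te_copies_per_family = as.integer(te_copies_per_family),
    satellite_unit = as.integer(satellite_unit),
    satellite_copies = as.integer(satellite_copies),
    n_blacklist_loci = as.integer(n_blacklist_loci),
    blacklist_len = as.integer(blacklist_len),
    uniqueness_k = as.integer(uniqueness_k),
    n_contigs = as.integer(n_contigs), spacer_len = as.integer(spacer_len),
    seed = as.integer(seed)
  ), class = "genome_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all k-mers of all contigs as a data.table(contig, pos0, kmer)
.genome_kmers <- function(contigs, k) {
  rbindlist(lapply(names(contigs), function(cn) {
    s <- contigs[[cn]]
    L <- nchar(s)
    if (L < k) return(NULL)
    n <- L - k + 1L
    data.table(contig = cn, pos = 0:(n - 1L),
               kmer = substring(s, 1:n, k:L))
  }))
}

# point-mutate duplicated canonical k-mers until every k-mer (up to reverse
# complement) occurs once genome-wide; bounded number of repair rounds
.enforce_kmer_uniqueness <- function(contigs, k, max_rounds = 50L) {
  for (round in seq_len(max_rounds)) {
    km <- .genome_kmers(contigs, k)
    km[, kmer := pmin(kmer, revcomp(kmer))]
    dup <- km[duplicated(kmer) | duplicated(kmer, fromLast = TRUE)]
    if (nrow(dup) == 0L) return(contigs)
    # keep the first occurrence of each duplicated canonical k-mer,
    # mutate one base inside every later occurrence
    setorder(dup, kmer, contig, pos)
    fix <- dup[duplicated(kmer)]
    for (i in seq_len(nrow(fix))) {
      cn <- fix$contig[i]
      p <- fix$pos[i] + sample.int(k, 1L)   # 1-based position in window
      old <- substr(contigs[[cn]], p, p)
      substr(contigs[[cn]], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  stop("could not satisfy k-mer uniqueness after ", max_rounds,
       " repair rounds; feature spec too dense for k=", k, call. = FALSE)
}

#' Forge a synthetic annotated genome
#'
#' Generates random contigs carrying non-overlapping gene models (5'UTR,
#' alternating CDS-exons and introns, 3'UTR, parts abutting without gaps, on
#' a random strand), transposon copies (each family on both strands),
#' satellite loci and ncRNA blacklist loci, separated by random spacers.
#' Every genomic k-mer of length `uniqueness_k` is unique genome-wide up to
#' reverse complement, so reads at least that long map to exactly one locus.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `annotated_genome`: a list with `contigs`
#'   (named character vector) and `features` (table as from [read_gff3()]).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, .build_genome_impl(spec))
}

.build_genome_impl <- function(spec) {
  blocks <- list()
  add_block <- function(len, feats) {
    blocks[[length(blocks) + 1L]] <<- list(len = len, feats = feats)
  }
  # gene models: parts listed in transcript order, laid left-to-right for +
  # genes and right-to-left for - genes
  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("gene%03d", g)
    strand <- sample(c("+", "-"), 1L)
    parts <- data.table(
      ftype = c("utr5",
                rep(c("exon", "intron"), spec$exons_per_gene)[
                  seq_len(2L * spec$exons_per_gene - 1L)],
                "utr3"),
      len = NA_integer_
    )
    parts[ftype == "utr5", len := spec$utr5_len]
    parts[ftype == "utr3", len := spec$utr3_len]
    parts[ftype == "exon", len := spec$exon_len]
    parts[ftype == "intron", len := spec$intron_len]
    if (strand == "-") parts <- parts[rev(seq_len(.N))]
    parts[, end := cumsum(len)]
    parts[, start := end - len]
    parts[, id := sprintf("%s_%s%d", gid, ftype, seq_len(.N)), by = ftype]
    feats <- parts[, .(start, end, strand = strand, ftype, id,
                       gene_id = gid, family = NA_character_,
                       class = NA_character_)]
    add_block(sum(parts$len), feats)
  }
  # transposon copies: distinct random sequence per copy, strands alternate
  if (spec$n_te_families > 0L) {
    n_ltr <- round(spec$te_class_mix[["LTR"]] * spec$n_te_families)
    fam_class <- c(rep("LTR", n_ltr), rep("LINE", spec$n_te_families - n_ltr))
    for (f in seq_len(spec$n_te_families)) {
      fam <- sprintf("TEfam%02d", f)
      for (cpy in seq_len(spec$te_copies_per_family)) {
        len <- sample(spec$te_len_range[1]:spec$te_len_range[2], 1L)
        strand <- if (cpy %% 2L == 1L) "+" else "-"
        add_block(len, data.table(
          start = 0L, end = len, strand = strand, ftype = "transposon",
          id = sprintf("%s_c%d", fam, cpy), gene_id = NA_character_,
          family = fam, class = fam_class[f]))
      }
    }
  }
  for (s in seq_len(spec$satellite_copies)) {
    add_block(spec$satellite_unit, data.table(
      start = 0L, end = spec$satellite_unit, strand = sample(c("+", "-"), 1L),
      ftype = "satellite", id = sprintf("sat%02d", s),
      gene_id = NA_character_, family = NA_character_, class = NA_character_))
  }
  for (cls in blacklist_ftypes) {
    for (b in seq_len(spec$n_blacklist_loci)) {
      add_block(spec$blacklist_len, data.table(
        start = 0L, end = spec$blacklist_len, strand = sample(c("+", "-"), 1L),
        ftype = cls, id = sprintf("%s%02d", cls, b),
        gene_id = NA_character_, family = NA_character_,
        class = NA_character_))
    }
  }
  # distribute shuffled blocks over contigs with random spacers
  if (length(blocks)) blocks <- blocks[sample.int(length(blocks))]
  contig_of <- if (length(blocks)) {
    rep_len(seq_len(spec$n_contigs), length(blocks))
  } else integer(0)
  contigs <- character(spec$n_contigs)
  names(contigs) <- sprintf("chrS%d", seq_len(spec$n_contigs))
  feats_all <- list()
  for (ci in seq_len(spec$n_contigs)) {
    offset <- 0L
    pieces <- character(0)
    spacer <- function() max(spec$spacer_len, spec$uniqueness_k)
    sp <- random_dna(spacer()); pieces <- c(pieces, sp); offset <- offset + nchar(sp)
    for (bi in which(contig_of == ci)) {
      b <- blocks[[bi]]
      pieces <- c(pieces, random_dna(b$len))
      f <- copy(b$feats)
      f[, `:=`(start = start + offset, end = end + offset,
               contig = names(contigs)[ci])]
      feats_all[[length(feats_all) + 1L]] <- f
      offset <- offset + b$len
      sp <- random_dna(spacer()); pieces <- c(pieces, sp); offset <- offset + nchar(sp)
    }
    contigs[ci] <- paste(pieces, collapse = "")
  }
  contigs <- as.list(contigs)
  contigs <- .enforce_kmer_uniqueness(contigs, spec$uniqueness_k)
  contigs <- unlist(contigs)
  features <- if (length(feats_all)) {
    out <- rbindlist(feats_all)
    setcolorder(out, c("contig", "start", "end", "strand", "ftype", "id",
                       "gene_id", "family", "class"))
    setorder(out, contig, start)
    out[]
  } else {
    data.table(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), ftype = character(0), id = character(0),
               gene_id = character(0), family = character(0),
               class = character(0))
  }
  structure(list(contigs = contigs, features = features, spec = spec),
            class = "annotated_genome")
}

#' Write an annotated genome as FASTA + GFF3
#'
#' @param genome an `annotated_genome`.
#' @param fasta_path,gff3_path output paths.
#' @return the two paths, invisibly.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  write_fasta(genome$contigs, fasta_path)
  write_gff3(genome$features, gff3_path)
  invisible(c(fasta_path, gff3_path))
}

#' Read-population profile for the small-RNA simulator
#'
#' Defines the planted composition of a simulated piRNA library: the
#' category mixture over transposon/satellite/genic/blacklist origins, the
#' genic feature mixture (CDS-exon/intron/5'UTR/3'UTR), the transposon
#' sense fraction, the read-length distribution over 23-29 nt, and the
#' fraction of transposon reads drawn from planted ping-pong pairs (species
#' pairs on opposite strands whose 5' ends overlap by exactly 10 nt).
#'
#' @param category_mix proportions over
#'   `c(transposon=, satellite=, genic=, blacklist=)`.
#' @param genic_feature_mix proportions over
#'   `c(exon=, intron=, utr5=, utr3=)`.
#' @param te_sense_fraction probability that a (non-ping-pong) transposon
#'   read is sense to its element.
#' @param length_dist named probability vector over read lengths (support
#'   must lie in 18-35 nt).
#' @param pingpong_pair_fraction fraction of transposon reads drawn from
#'   planted 10-nt-overlap species pairs.
#' @param genic_sense_fraction probability that a genic read is sense to its
#'   gene (artifact default 0.5; not a published value).
#' @param mean_species_count target mean pooled count per planted piRNA
#'   species; controls how many distinct species carry each mixture cell.
#' @param seed RNG seed.
#' @return an object of class `read_profile`.
#' @export
read_profile <- function(category_mix = c(transposon = 0.25, satellite = 0.05,
                                          genic = 0.6, blacklist = 0.1),
                         genic_feature_mix = c(exon = 0.4, intron = 0.3,
                                               utr5 = 0.1, utr3 = 0.2),
                         te_sense_fraction = 0.5,
                         length_dist = setNames(
                           c(0.06, 0.12, 0.18, 0.28, 0.18, 0.12, 0.06),
                           23:29),
                         pingpong_pair_fraction = 0,
                         genic_sense_fraction = 0.5,
                         mean_species_count = 25,
                         seed = 1L) {
  check_proportions(category_mix[c("transposon", "satellite", "genic", "blacklist")],
                    "category_mix")
  check_proportions(genic_feature_mix[c("exon", "intron", "utr5", "utr3")],
                    "genic_feature_mix")
  check_proportions(length_dist, "length_dist")
  lens <- as.integer(names(length_dist))
  if (any(is.na(lens)) || any(lens[length_dist > 0] < 18) ||
      any(lens[length_dist > 0] > 35)) {
    stop("length_dist support must lie within 18-35 nt", call. = FALSE)
  }
  stopifnot(te_sense_fraction >= 0, te_sense_fraction <= 1,
            pingpong_pair_fraction >= 0, pingpong_pair_fraction <= 1,
            genic_sense_fraction >= 0, genic_sense_fraction <= 1,
            mean_species_count >= 1)
  structure(list(
    category_mix = category_mix[c("transposon", "satellite", "genic", "blacklist")],
    genic_feature_mix = genic_feature_mix[c("exon", "intron", "utr5", "utr3")],
    te_sense_fraction = te_sense_fraction,
    length_dist = length_dist,
    pingpong_pair_fraction = pingpong_pair_fraction,
    genic_sense_fraction = genic_sense_fraction,
    mean_species_count = mean_species_count,
    seed = as.integer(seed)
  ), class = "read_profile")
}

#' Brain-tissue read-profile preset
#'
#' Mostly genic piRNAs (87.8%), ~10% transposon with a 0.70 sense fraction,
#' 0.2% satellite and 2% blacklist contamination; genic reads favour
#' CDS-exons (62%) and 3'UTRs (22%); no planted ping-pong pairing. The
#' genic intron/5'UTR split (11%/5%), the numeric sense fraction and the
#' blacklist share are artifact defaults, not published values.
#'
#' @param ... overrides passed to [read_profile()].
#' @return a `read_profile`.
#' @export
profile_brain <- function(...) {
  args <- list(
    category_mix = c(transposon = 0.10, satellite = 0.002,
                     genic = 0.878, blacklist = 0.02),
    genic_feature_mix = c(exon = 0.62, intron = 0.11, utr5 = 0.05, utr3 = 0.22),
    te_sense_fraction = 0.70,
    pingpong_pair_fraction = 0,
    seed = 101L
  )
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(read_profile, args)
}

#' Ovary-tissue read-profile preset
#'
#' Transposon-dominated (90%) with an antisense bias (sense fraction 0.30),
#' 2.3% satellite, 5.7% genic favouring introns (66%), 2% blacklist, and 30%
#' of transposon reads drawn from planted ping-pong pairs. The numeric sense
#' fraction and blacklist share are artifact defaults, not published values.
#'
#' @param ... overrides passed to [read_profile()].
#' @return a `read_profile`.
#' @export
profile_ovary <- function(...) {
  args <- list(
    category_mix = c(transposon = 0.90, satellite = 0.023,
                     genic = 0.057, blacklist = 0.02),
    genic_feature_mix = c(exon = 0.12, intron = 0.66, utr5 = 0.15, utr3 = 0.07),
    te_sense_fraction = 0.30,
    pingpong_pair_fraction = 0.30,
    seed = 102L
  )
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(read_profile, args)
}

#' Mutant-brain read-profile preset (sense bias eliminated)
#'
#' Identical to [profile_brain()] except the transposon sense fraction is
#' 0.5: the population whose strand parity the bias test should not reject.
#'
#' @param ... overrides passed to [read_profile()].
#' @return a `read_profile`.
#' @export
profile_tud_brain <- function(...) {
  profile_brain(te_sense_fraction = 0.5, seed = 103L, ...)
}

# build a pool of planted piRNA species for one mixture cell
.make_species <- function(genome, feats, n_species, orient, lens, lprob, cell) {
  if (n_species == 0L) return(NULL)
  maxlen <- max(lens[lprob > 0])
  ok <- feats[(end - start) >= maxlen]
  if (nrow(ok) == 0L) {
    stop("requested read length ", maxlen,
         " exceeds every source feature length for cell '", cell, "'",
         call. = FALSE)
  }
  fi <- ok[sample.int(.N, n_species, replace = TRUE)]
  len <- sample(lens, n_species, replace = TRUE, prob = lprob)
  off <- floor(runif(n_species) * (fi$end - fi$start - len + 1L))
  aln_strand <- if (orient == "sense") fi$strand else chartr("+-", "-+", fi$strand)
  st <- fi$start + as.integer(off)
  en <- st + len
  sq <- substring(genome$contigs[fi$contig], st + 1L, en)
  sq <- ifelse(aln_strand == "-", revcomp(sq), sq)
  data.table(cell = cell, category = fifelse(fi$ftype %in% gene_part_ftypes,
                                             "genic",
                                             fifelse(fi$ftype == "transposon",
                                                     "transposon",
                                                     fifelse(fi$ftype == "satellite",
                                                             "satellite", "blacklist"))),
             feature = fifelse(fi$ftype %in% gene_part_ftypes, fi$ftype, "none"),
             sense = orient, source_feature_id = fi$id,
             contig = fi$contig, start = st, end = en, strand = aln_strand,
             length = len, seq = sq, pingpong = FALSE)
}

# planted ping-pong species pairs inside transposon copies: the + member's
# 5' end at p, the - member's 5' end at p+9, so the 5'-5' overlap is 10 nt
.make_pp_pairs <- function(genome, te_feats, n_pairs, lens, lprob) {
  if (n_pairs == 0L) return(NULL)
  maxlen <- max(lens[lprob > 0])
  ok <- te_feats[(end - start) >= (2L * maxlen)]
  if (nrow(ok) == 0L) {
    stop("transposon copies too short to host ping-pong pairs", call. = FALSE)
  }
  fi <- ok[sample.int(.N, n_pairs, replace = TRUE)]
  l1 <- sample(lens, n_pairs, replace = TRUE, prob = lprob)
  l2 <- sample(lens, n_pairs, replace = TRUE, prob = lprob)
  lo <- fi$start + pmax(0L, l2 - 10L)
  hi <- fi$end - l1
  p <- lo + as.integer(floor(runif(n_pairs) * (hi - lo + 1L)))
  plus <- data.table(contig = fi$contig, start = p, end = p + l1,
                     strand = "+", length = l1,
                     source_feature_id = fi$id, feat_strand = fi$strand)
  minus <- data.table(contig = fi$contig, start = p + 10L - l2, end = p + 10L,
                      strand = "-", length = l2,
                      source_feature_id = fi$id, feat_strand = fi$strand)
  both <- rbind(plus, minus)
  sq <- substring(genome$contigs[both$contig], both$start + 1L, both$end)
  both[, seq := fifelse(strand == "-", revcomp(sq), sq)]
  both[, `:=`(cell = "te_pp", category = "transposon", feature = "none",
              sense = fifelse(strand == feat_strand, "sense", "antisense"),
              pingpong = TRUE)]
  both[, feat_strand := NULL]
  setcolorder(both, c("cell", "category", "feature", "sense",
                      "source_feature_id", "contig", "start", "end",
                      "strand", "length", "seq", "pingpong"))
  both[]
}

#' Simulate a small-RNA read population with planted truth
#'
#' Draws `n_reads` read instances. Each instance independently draws its
#' category from `category_mix`, then (for genic reads) a gene part from
#' `genic_feature_mix` and a sense orientation, or (for transposon reads)
#' membership in a planted ping-pong pair versus a sense/antisense single
#' species. Instances then pick a planted species — a fixed (locus, length,
#' strand) — uniformly within their cell, which concentrates counts on a
#' realistic number of distinct sequences so the minimum-count filter is
#' satisfiable. Every read is an exact substring (or reverse complement) of
#' its source feature.
#'
#' @param genome an `annotated_genome` from [build_genome()].
#' @param profile a [read_profile()].
#' @param n_reads total number of read instances.
#' @param n_samples number of samples the instances are distributed over
#'   uniformly at random.
#' @param seed RNG seed; defaults to the profile's.
#' @return a `data.table`, one row per read instance, with columns
#'   `sample_id`, `seq`, `length`, `category`, `feature`, `sense`,
#'   `source_feature_id`, `contig`, `start`, `end`, `strand` (the planted
#'   genomic placement) and `pingpong`; the planted species table is kept in
#'   the `species` attribute.
#' @export
simulate_reads <- function(genome, profile, n_reads, n_samples = 1L,
                           seed = profile$seed) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(profile, "read_profile"), n_reads >= 1, n_samples >= 1)
  with_seed(seed, .simulate_reads_impl(genome, profile, n_reads, n_samples))
}

.simulate_reads_impl <- function(genome, profile, n_reads, n_samples) {
  ft <- genome$features
  mix <- profile$category_mix
  for (cat in names(mix)[mix > 0]) {
    have <- switch(cat,
      transposon = any(ft$ftype == "transposon"),
      satellite = any(ft$ftype == "satellite"),
      genic = any(ft$ftype %in% gene_part_ftypes),
      blacklist = any(ft$ftype %in% blacklist_ftypes))
    if (!have) stop("genome has no '", cat, "' feature but category_mix[",
                    cat, "] > 0", call. = FALSE)
  }
  lens <- as.integer(names(profile$length_dist))
  lprob <- as.numeric(profile$length_dist)
  msc <- profile$mean_species_count
  pp <- profile$pingpong_pair_fraction
  f <- profile$te_sense_fraction
  gsf <- profile$genic_sense_fraction
  gmix <- profile$genic_feature_mix
  pool_n <- function(expected) if (expected <= 0) 0L else max(1L, as.integer(round(expected / msc)))

  te_feats <- ft[ftype == "transposon"]
  sat_feats <- ft[ftype == "satellite"]
  bl_feats <- ft[ftype %in% blacklist_ftypes]
  species <- list()
  addsp <- function(x) if (!is.null(x)) species[[length(species) + 1L]] <<- x
  if (mix[["transposon"]] > 0) {
    e_te <- n_reads * mix[["transposon"]]
    addsp(.make_species(genome, te_feats, pool_n(e_te * (1 - pp) * f),
                        "sense", lens, lprob, "te_sense"))
    addsp(.make_species(genome, te_feats, pool_n(e_te * (1 - pp) * (1 - f)),
                        "antisense", lens, lprob, "te_anti"))
    addsp(.make_pp_pairs(genome, te_feats, pool_n(e_te * pp / 2), lens, lprob))
  }
  if (mix[["satellite"]] > 0) {
    addsp(.make_species(genome, sat_feats, pool_n(n_reads * mix[["satellite"]]),
                        "sense", lens, lprob, "satellite"))
  }
  if (mix[["blacklist"]] > 0) {
    addsp(.make_species(genome, bl_feats, pool_n(n_reads * mix[["blacklist"]]),
                        "sense", lens, lprob, "blacklist"))
  }
  if (mix[["genic"]] > 0) {
    for (part in names(gmix)[gmix > 0]) {
      e_part <- n_reads * mix[["genic"]] * gmix[[part]]
      pf <- ft[ftype == part]
      if (nrow(pf) == 0L) stop("genome has no '", part, "' gene part",
                               call. = FALSE)
      addsp(.make_species(genome, pf, pool_n(e_part * gsf),
                          "sense", lens, lprob, paste0("genic_", part, "_s")))
      addsp(.make_species(genome, pf, pool_n(e_part * (1 - gsf)),
                          "antisense", lens, lprob, paste0("genic_", part, "_a")))
    }
  }
  species <- rbindlist(species)
  species[, species_id := sprintf("sp%05d", .I)]

  # instance-level draws: category, then cell, then species within cell
  cat_draw <- sample(names(mix), n_reads, replace = TRUE, prob = mix)
  cell_draw <- character(n_reads)
  is_te <- cat_draw == "transposon"
  n_te <- sum(is_te)
  if (n_te > 0) {
    ppflag <- runif(n_te) < pp
    sflag <- runif(n_te) < f
    cell_draw[is_te] <- fifelse(ppflag, "te_pp",
                                fifelse(sflag, "te_sense", "te_anti"))
  }
  is_gen <- cat_draw == "genic"
  n_gen <- sum(is_gen)
  if (n_gen > 0) {
    part <- sample(names(gmix), n_gen, replace = TRUE, prob = gmix)
    orient <- ifelse(runif(n_gen) < gsf, "s", "a")
    cell_draw[is_gen] <- paste0("genic_", part, "_", orient)
  }
  cell_draw[cat_draw == "satellite"] <- "satellite"
  cell_draw[cat_draw == "blacklist"] <- "blacklist"

  sp_by_cell <- split(seq_len(nrow(species)), species$cell)
  pick <- integer(n_reads)
  for (cl in unique(cell_draw)) {
    rows <- sp_by_cell[[cl]]
    if (is.null(rows)) {
      # a cell can be empty only when its pool size rounded to zero while a
      # rare instance still drew it; fall back to the nearest sibling cell
      sib <- grep(paste0("^", sub("_[sa]$", "", cl)), names(sp_by_cell), value = TRUE)
      rows <- unlist(sp_by_cell[sib], use.names = FALSE)
      if (is.null(rows) || length(rows) == 0L) {
        stop("no planted species available for cell '", cl, "'", call. = FALSE)
      }
    }
    idx <- which(cell_draw == cl)
    pick[idx] <- rows[sample.int(length(rows), length(idx), replace = TRUE)]
  }
  out <- species[pick, .(seq, length, category, feature, sense,
                         source_feature_id, contig, start, end, strand,
                         pingpong, species_id)]
  out[, sample_id := sprintf("sample%d", sample.int(n_samples, .N, replace = TRUE))]
  setcolorder(out, c("sample_id", "seq", "length", "category", "feature",
                     "sense", "source_feature_id", "contig", "start", "end",
                     "strand", "pingpong", "species_id"))
  setattr(out, "species", species)
  out[]
}

#' Split simulated reads into per-sample sequence vectors
#'
#' @param sim a table from [simulate_reads()].
#' @return named list of character vectors, one per sample.
#' @export
reads_by_sample <- function(sim) {
  split(sim$seq, sim$sample_id)
}

#' Truth labels for collapsed reads
#'
#' Joins a collapsed-read table back to the planted truth by sequence (the
#' genome's k-mer uniqueness makes sequence a key for the planted label).
#'
#' @param reads a table from [collapse_reads()].
#' @param sim the simulation the reads came from.
#' @return a `data.table` keyed by `id` with the planted `category`,
#'   `feature`, `sense`, `source_feature_id` and `pingpong` flag.
#' @export
truth_for_reads <- function(reads, sim) {
  truth <- unique(as.data.table(sim)[, .(seq, category, feature, sense,
                                         source_feature_id, pingpong)],
                  by = "seq")
  out <- merge(data.table(id = reads$id, seq = reads$seq), truth,
               by = "seq", all.x = TRUE, sort = FALSE)
  setcolorder(out, c("id", "seq"))
  out[]
}

#' Plan for simulating replicate count matrices with planted DE
#'
#' Negative-binomial counts (variance mu + phi*mu^2) for two groups of
#' replicates; a `de_fraction` of features changes in group B by
#' `2^(+/- log2fc_magnitude)`, the sign drawn so that `down_fraction_among_de`
#' of DE features go down.
#'
#' @param n_features number of features.
#' @param de_fraction fraction of features that are truly DE.
#' @param down_fraction_among_de fraction of DE features that are
#'   downregulated in group B.
#' @param log2fc_magnitude absolute planted log2 fold change.
#' @param baseline_mean group-A mean count.
#' @param dispersion NB dispersion phi (> 0).
#' @param replicates_per_group replicates per group (>= 2).
#' @param seed RNG seed.
#' @return an object of class `de_plan`.
#' @export
de_plan <- function(n_features = 2000, de_fraction = 0.3,
                    down_fraction_among_de = 0.5, log2fc_magnitude = 3,
                    baseline_mean = 100, dispersion = 0.1,
                    replicates_per_group = 3, seed = 1L) {
  stopifnot(n_features >= 1, de_fraction >= 0, de_fraction <= 1,
            down_fraction_among_de >= 0, down_fraction_among_de <= 1,
            log2fc_magnitude > 0, baseline_mean > 0, dispersion > 0,
            replicates_per_group >= 2)
  structure(list(n_features = as.integer(n_features),
                 de_fraction = de_fraction,
                 down_fraction_among_de = down_fraction_among_de,
                 log2fc_magnitude = log2fc_magnitude,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 replicates_per_group = as.integer(replicates_per_group),
                 seed = as.integer(seed)),
            class = "de_plan")
}

#' Brain differential-expression plan preset (85\% of DE features down)
#' @param ... overrides passed to [de_plan()].
#' @return a `de_plan`.
#' @export
de_plan_brain <- function(...) {
  args <- list(down_fraction_among_de = 0.85, seed = 11L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(de_plan, args)
}

#' Ovary differential-expression plan preset (39\% of DE features down)
#' @param ... overrides passed to [de_plan()].
#' @return a `de_plan`.
#' @export
de_plan_ovary <- function(...) {
  args <- list(down_fraction_among_de = 0.39, seed = 13L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(de_plan, args)
}

#' Simulate a replicate count matrix with planted differential expression
#'
#' @param plan a [de_plan()].
#' @return a list with `counts` (integer matrix, features x samples, group-A
#'   columns first), `groups` (factor of "A"/"B" per column) and `truth`
#'   (`data.table` of feature id, planted direction in up/down/null, and
#'   planted log2 fold change).
#' @export
simulate_counts <- function(plan) {
  stopifnot(inherits(plan, "de_plan"))
  with_seed(plan$seed, {
    n <- plan$n_features
    r <- plan$replicates_per_group
    is_de <- runif(n) < plan$de_fraction
    down <- is_de & (runif(n) < plan$down_fraction_among_de)
    lfc <- numeric(n)
    lfc[is_de & !down] <- plan$log2fc_magnitude
    lfc[down] <- -plan$log2fc_magnitude
    muA <- rep(plan$baseline_mean, n)
    muB <- plan$baseline_mean * 2^lfc
    size <- 1 / plan$dispersion
    cA <- matrix(rnbinom(n * r, size = size, mu = rep(muA, r)), nrow = n)
    cB <- matrix(rnbinom(n * r, size = size, mu = rep(muB, r)), nrow = n)
    counts <- cbind(cA, cB)
    rownames(counts) <- sprintf("feat%05d", seq_len(n))
    colnames(counts) <- c(sprintf("A%d", seq_len(r)), sprintf("B%d", seq_len(r)))
    groups <- factor(rep(c("A", "B"), each = r))
    truth <- data.table(feature_id = rownames(counts),
                        direction = fifelse(!is_de, "null",
                                            fifelse(down, "down", "up")),
                        log2fc = lfc)
    list(counts = counts, groups = groups, truth = truth)
  })
}

#' Plant a joint piRNA/gene differential-expression concordance structure
#'
#' Fabricates the three tables the concordance analysis consumes — piRNA DE
#' results, genic antisense assignments, and a gene-level DE table — with a
#' planted quadrant structure: each piRNA targets one gene; a
#' `down_fraction` of piRNAs are downregulated; the targeted gene moves in
#' the opposite direction with probability `anti_fraction`.
#'
#' @param n_pirnas number of significant antisense piRNAs (= pairs planted).
#' @param down_fraction fraction of piRNAs downregulated.
#' @param anti_fraction probability that the target gene's direction is
#'   opposite the piRNA's.
#' @param n_null_genes additional non-significant genes appended to the gene
#'   table.
#' @param seed RNG seed.
#' @return list of `pirna_de`, `assignments`, `gene_de` tables and the
#'   planted `truth`.
#' @export
simulate_concord_plant <- function(n_pirnas = 500, down_fraction = 0.85,
                                   anti_fraction = 0.8, n_null_genes = 100,
                                   seed = 1L) {
  with_seed(seed, {
    pid <- sprintf("piR%06d", seq_len(n_pirnas))
    gid <- sprintf("geneC%04d", seq_len(n_pirnas))
    p_down <- runif(n_pirnas) < down_fraction
    p_lfc <- ifelse(p_down, -1, 1) * runif(n_pirnas, 0.5, 3)
    anti <- runif(n_pirnas) < anti_fraction
    g_up <- ifelse(p_down, anti, !anti)   # gene up iff direction opposes piRNA when anti
    g_lfc <- ifelse(g_up, 1, -1) * runif(n_pirnas, 0.5, 3)
    pirna_de <- data.table(feature_id = pid, log2fc = p_lfc,
                           p = runif(n_pirnas, 0, 1e-4),
                           q = runif(n_pirnas, 0, 1e-3),
                           direction = ifelse(p_down, "down", "up"))
    assignments <- data.table(read_id = pid, category = "genic",
                              te_class = "none",
                              feature = sample(gene_part_ftypes, n_pirnas,
                                               replace = TRUE),
                              sense = "antisense", target_id = gid,
                              weight = sample(10:200, n_pirnas, replace = TRUE))
    gene_sig <- data.table(gene_id = gid, log2fc = g_lfc,
                           p = runif(n_pirnas, 0, 1e-4),
                           q = runif(n_pirnas, 0, 0.04),
                           direction = ifelse(g_up, "up", "down"))
    gene_null <- data.table(gene_id = sprintf("geneN%04d", seq_len(n_null_genes)),
                            log2fc = runif(n_null_genes, -0.5, 0.5),
                            p = runif(n_null_genes, 0.2, 1),
                            q = runif(n_null_genes, 0.3, 1),
                            direction = "ns")
    list(pirna_de = pirna_de, assignments = assignments,
         gene_de = rbind(gene_sig, gene_null),
         truth = data.table(pirna_id = pid, gene_id = gid,
                            pirna_down = p_down, gene_up = g_up))
  })
}
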