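#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' study design the pipeline was built for: two groups of 40 PBMC samples,
#' four RNA classes, negative-binomial counts around log-normal baselines
#' (dispersion 0.1), planted |log2FC| = 2 effects in 5% of features per
#' class, and 20 planted sponge-miRNA-mRNA triads whose sequences carry real
#' 8mer seed sites. Feature counts are desk-scale (hundreds, not the tens of
#' thousands of a full transcriptome) so the whole pipeline runs in seconds.
#'
#' @param n_case,n_control Samples per group.
#' @param n_features Named integer vector, features per RNA class.
#' @param nb_dispersion Negative-binomial dispersion (reciprocal of `size`);
#'   0 gives Poisson counts.
#' @param baseline_logmean_mu,baseline_logmean_sigma Log-normal parameters of
#'   per-feature baseline mean counts.
#' @param de_fraction Fraction of features per class given a planted effect
#'   (in addition to planted-triad members). Scalar or named per-class vector.
#' @param de_log2fc Magnitude of planted log2 fold changes.
#' @param n_planted_triads Number of planted sponge-miRNA-mRNA triads; sponge
#'   classes alternate between lncRNA and circRNA.
#' @param utr_length,lnc_length,circ_length,mirna_length Sequence lengths (nt).
#' @param background_reads Unassigned mapped reads added to every sample's
#'   column-sum to form its mapped total.
#' @param seed Integer RNG seed; all randomness flows from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_case = 40L, n_control = 40L,
                       n_features = c(mRNA = 400L, lncRNA = 150L,
                                      circRNA = 80L, miRNA = 100L),
                       nb_dispersion = 0.1,
                       baseline_logmean_mu = 4, baseline_logmean_sigma = 1,
                       de_fraction = 0.05, de_log2fc = 2,
                       n_planted_triads = 20L,
                       utr_length = 500L, lnc_length = 800L,
                       circ_length = 400L, mirna_length = 22L,
                       background_reads = 1e6, seed = 1L) {
  if (length(de_fraction) == 1L) {
    de_fraction <- setNames(rep(de_fraction, 4), RNA_CLASSES)
  }
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_features = setNames(as.integer(n_features[RNA_CLASSES]), RNA_CLASSES),
              nb_dispersion = nb_dispersion,
              baseline_logmean_mu = baseline_logmean_mu,
              baseline_logmean_sigma = baseline_logmean_sigma,
              de_fraction = de_fraction[RNA_CLASSES],
              de_log2fc = de_log2fc,
              n_planted_triads = as.integer(n_planted_triads),
              utr_length = as.integer(utr_length),
              lnc_length = as.integer(lnc_length),
              circ_length = as.integer(circ_length),
              mirna_length = as.integer(mirna_length),
              background_reads = background_reads,
              seed = as.integer(seed))
  if (cfg$n_case < 1L || cfg$n_control < 1L) stop_domain("need >=1 sample per group")
  if (any(is.na(cfg$n_features)) || any(cfg$n_features < 0L)) {
    stop_domain("n_features must name all of ", paste(RNA_CLASSES, collapse = ", "))
  }
  if (cfg$nb_dispersion < 0) stop_domain("nb_dispersion must be >= 0")
  if (any(is.na(cfg$de_fraction)) || any(cfg$de_fraction < 0) ||
      any(cfg$de_fraction > 1)) {
    stop_domain("de_fraction must lie in [0, 1]")
  }
  if (cfg$de_log2fc <= 0) stop_domain("de_log2fc must be positive")
  if (cfg$mirna_length < 19L) stop_domain("mirna_length must be >= 19")
  lens <- c(cfg$utr_length, cfg$lnc_length, cfg$circ_length)
  if (any(lens < 8L)) stop_domain("target sequences must hold an 8-nt site")
  if (cfg$n_planted_triads < 0L) stop_domain("n_planted_triads must be >= 0")
  if (cfg$n_planted_triads > 0L) {
    need <- c(mRNA = cfg$n_planted_triads, miRNA = cfg$n_planted_triads,
              lncRNA = ceiling(cfg$n_planted_triads / 2),
              circRNA = floor(cfg$n_planted_triads / 2))
    short <- need > cfg$n_features[names(need)]
    if (any(short)) {
      stop_domain("not enough ", paste(names(need)[short], collapse = "/"),
                  " features to host ", cfg$n_planted_triads, " planted triads")
    }
  }
  if (abs(cfg$seed) > 2^30) stop_domain("seed must fit comfortably in a 32-bit integer")
  structure(cfg, class = "sim_config")
}

feature_ids_for <- function(class, n) {
  if (n == 0L) return(character(0))
  sprintf("%s_%04d", class, seq_len(n))
}

# Deterministic plan shared by generate_sequences() and generate_counts():
# triad membership, direction patterns, planted DE effects, and per-feature
# baseline means. Re-derived from cfg$seed so the two generators agree even
# when called independently.
plan_truth <- function(cfg) {
  set.seed(cfg$seed)
  ids <- lapply(RNA_CLASSES, function(cl) feature_ids_for(cl, cfg$n_features[[cl]]))
  names(ids) <- RNA_CLASSES
  baselines <- lapply(RNA_CLASSES, function(cl) {
    setNames(rlnorm(cfg$n_features[[cl]], cfg$baseline_logmean_mu,
                    cfg$baseline_logmean_sigma), ids[[cl]])
  })
  names(baselines) <- RNA_CLASSES

  nt <- cfg$n_planted_triads
  triads <- data.frame(sponge_id = character(0), sponge_class = character(0),
                       mirna_id = character(0), mrna_id = character(0),
                       pattern = character(0), stringsAsFactors = FALSE)
  if (nt > 0L) {
    sponge_class <- rep(c("lncRNA", "circRNA"), length.out = nt)
    sponge_id <- character(nt)
    sponge_id[sponge_class == "lncRNA"] <-
      sample(ids$lncRNA, sum(sponge_class == "lncRNA"))
    sponge_id[sponge_class == "circRNA"] <-
      sample(ids$circRNA, sum(sponge_class == "circRNA"))
    triads <- data.frame(
      sponge_id = sponge_id, sponge_class = sponge_class,
      mirna_id = sample(ids$miRNA, nt),
      mrna_id = sample(ids$mRNA, nt),
      pattern = sample(c("up-down-up", "down-up-down"), nt, replace = TRUE),
      stringsAsFactors = FALSE)
  }

  # Planted effects: triad members get coordinated signs; an additional
  # de_fraction of non-member features per class get a random sign.
  effects <- list()
  add_effect <- function(id, class, lfc) {
    effects[[length(effects) + 1L]] <<- data.frame(
      feature_id = id, class = class, log2fc_planted = lfc,
      stringsAsFactors = FALSE)
  }
  if (nt > 0L) {
    up <- ifelse(triads$pattern == "up-down-up", 1, -1)
    add_effect(triads$sponge_id, triads$sponge_class, up * cfg$de_log2fc)
    add_effect(triads$mirna_id, rep("miRNA", nt), -up * cfg$de_log2fc)
    add_effect(triads$mrna_id, rep("mRNA", nt), up * cfg$de_log2fc)
  }
  for (cl in RNA_CLASSES) {
    taken <- if (nt > 0L) {
      unique(c(triads$sponge_id[triads$sponge_class == cl],
               if (cl == "miRNA") triads$mirna_id,
               if (cl == "mRNA") triads$mrna_id))
    } else character(0)
    pool <- setdiff(ids[[cl]], taken)
    n_extra <- floor(cfg$de_fraction[[cl]] * cfg$n_features[[cl]])
    n_extra <- min(n_extra, length(pool))
    if (n_extra > 0L) {
      chosen <- sample(pool, n_extra)
      add_effect(chosen, rep(cl, n_extra),
                 sample(c(-1, 1), n_extra, replace = TRUE) * cfg$de_log2fc)
    }
  }
  de_effects <- if (length(effects)) do.call(rbind, effects) else
    data.frame(feature_id = character(0), class = character(0),
               log2fc_planted = numeric(0), stringsAsFactors = FALSE)
  if (nrow(de_effects)) {
    bl <- unlist(baselines, use.names = FALSE)
    names(bl) <- unlist(ids, use.names = FALSE)
    de_effects$baseline_mean <- unname(bl[de_effects$feature_id])
  } else {
    de_effects$baseline_mean <- numeric(0)
  }
  list(ids = ids, baselines = baselines, triads = triads,
       de_effects = de_effects)
}

random_rna <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of an RNA string
#' @param x RNA string(s) over {A,C,G,U} (T accepted, mapped to U).
#' @return Reverse complement string(s).
#' @export
revcomp_rna <- function(x) {
  x <- chartr("Tt", "Uu", x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# The canonical 8mer site for a miRNA: reverse complement of positions 2-8,
# followed by an A opposite position 1.
mirna_8mer_site <- function(mirna_seq) {
  paste0(revcomp_rna(substr(mirna_seq, 2, 8)), "A")
}

#' Generate per-class sequences with planted seed sites
#'
#' Random-composition RNA sequences for every feature of every class;
#' circRNAs are flagged `topology=circular` (stored linearised, junction at
#' position 1). For each planted triad the miRNA's exact 8mer site is written
#' into both the sponge and the mRNA 3'UTR at a recorded 1-based position.
#'
#' @param cfg A [sim_config()].
#' @return A list with `sequences` (per class: named character vector),
#'   `topology` (per class), `site_plants` (data.frame: mirna_id, target_id,
#'   target_class, start, site_type), and `triads`.
#' @export
generate_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  plan <- plan_truth(cfg)
  set.seed(cfg$seed + 1L)
  lens <- c(mRNA = cfg$utr_length, lncRNA = cfg$lnc_length,
            circRNA = cfg$circ_length, miRNA = cfg$mirna_length)
  seqs <- lapply(RNA_CLASSES, function(cl) {
    setNames(random_rna(cfg$n_features[[cl]], lens[[cl]]), plan$ids[[cl]])
  })
  names(seqs) <- RNA_CLASSES

  plants <- list()
  if (nrow(plan$triads)) {
    for (i in seq_len(nrow(plan$triads))) {
      tri <- plan$triads[i, ]
      site <- mirna_8mer_site(seqs$miRNA[[tri$mirna_id]])
      for (spec in list(c(tri$sponge_id, tri$sponge_class),
                        c(tri$mrna_id, "mRNA"))) {
        tid <- spec[1]; tcl <- spec[2]
        tlen <- nchar(seqs[[tcl]][[tid]])
        if (tlen < nchar(site)) {
          stop_domain("planted site longer than target sequence ", tid)
        }
        pos <- sample.int(tlen - nchar(site) + 1L, 1L)
        substr(seqs[[tcl]][[tid]], pos, pos + nchar(site) - 1L) <- site
        plants[[length(plants) + 1L]] <- data.frame(
          mirna_id = tri$mirna_id, target_id = tid, target_class = tcl,
          start = pos, site_type = "8mer", stringsAsFactors = FALSE)
      }
    }
  }
  site_plants <- if (length(plants)) do.call(rbind, plants) else
    data.frame(mirna_id = character(0), target_id = character(0),
               target_class = character(0), start = integer(0),
               site_type = character(0), stringsAsFactors = FALSE)
  list(sequences = seqs,
       topology = c(mRNA = "linear", lncRNA = "linear",
                    circRNA = "circular", miRNA = "linear"),
       site_plants = site_plants, triads = plan$triads)
}

#' Generate count matrices, mapped totals, and the planted-effect truth
#'
#' Counts are negative-binomial around log-normal per-feature baselines.
#' Planted features have their case-group mean multiplied by
#' `2^(log2fc_planted)`; triad members carry coordinated signs (sponge and
#' mRNA share a sign, the miRNA takes the opposite one). Per-sample mapped
#' totals are the column sums over all classes plus `background_reads`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (per class [count_matrix()]), `sample_map`,
#'   `mapped_totals` (named numeric), `de_effects`, and `triads`.
#' @export
generate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  plan <- plan_truth(cfg)
  set.seed(cfg$seed + 2L)
  samples <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
               sprintf("ctrl_%02d", seq_len(cfg$n_control)))
  groups <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  lfc <- setNames(plan$de_effects$log2fc_planted, plan$de_effects$feature_id)

  draw <- function(n, mu) {
    if (cfg$nb_dispersion <= 0) rpois(n, mu)
    else rnbinom(n, size = 1 / cfg$nb_dispersion, mu = mu)
  }
  counts <- lapply(RNA_CLASSES, function(cl) {
    nf <- cfg$n_features[[cl]]
    m <- matrix(0, nrow = nf, ncol = length(samples),
                dimnames = list(plan$ids[[cl]], samples))
    if (nf > 0L) {
      base <- plan$baselines[[cl]]
      eff <- lfc[plan$ids[[cl]]]
      eff[is.na(eff)] <- 0
      mu_case <- base * 2^eff
      for (j in seq_along(samples)) {
        mu <- if (groups[j] == "case") mu_case else base
        m[, j] <- draw(nf, mu)
      }
    }
    count_matrix(m, cl)
  })
  names(counts) <- RNA_CLASSES
  totals <- Reduce(`+`, lapply(counts, function(cm) colSums(cm$counts)))
  totals <- totals + cfg$background_reads
  list(counts = counts,
       sample_map = data.frame(sample_id = samples, group = groups,
                               stringsAsFactors = FALSE),
       mapped_totals = totals,
       de_effects = plan$de_effects, triads = plan$triads)
}

#' Simulate a complete synthetic ceRNA dataset
#'
#' @param cfg A [sim_config()].
#' @return A `cerna_sim` object bundling the config, sequences, counts,
#'   sample map, mapped totals, and the [TruthSet][generate_counts] (planted
#'   effects, triads, site plants).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  sq <- generate_sequences(cfg)
  ct <- generate_counts(cfg)
  structure(list(cfg = cfg, sequences = sq$sequences, topology = sq$topology,
                 counts = ct$counts, sample_map = ct$sample_map,
                 mapped_totals = ct$mapped_totals,
                 truth = list(de_effects = ct$de_effects, triads = ct$triads,
                              site_plants = sq$site_plants)),
            class = "cerna_sim")
}

#' @export
print.cerna_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic ceRNA dataset: %d case / %d control samples; %s; %d planted triads\n",
    x$cfg$n_case, x$cfg$n_control,
    paste(sprintf("%d %s", x$cfg$n_features, names(x$cfg$n_features)),
          collapse = ", "),
    nrow(x$truth$triads)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits per-class FASTA, per-class count TSVs, the sample map, mapped
#' totals, and the truth set (TSV per table plus a combined JSON), and
#' returns a manifest listing every file with its row count.
#'
#' @param dataset A `cerna_sim` from [simulate_dataset()].
#' @param out_dir Output directory (created if absent).
#' @return Manifest `data.frame` with columns `file`, `rows`.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "cerna_sim"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  prov <- provenance_line("synthdata", list(seed = dataset$cfg$seed))
  manifest <- list()
  note <- function(file, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, rows = rows, stringsAsFactors = FALSE)
  }
  for (cl in RNA_CLASSES) {
    fa <- file.path(out_dir, paste0(tolower(cl), ".fa"))
    write_fasta(names(dataset$sequences[[cl]]), dataset$sequences[[cl]], fa,
                class = cl, topology = dataset$topology[[cl]])
    note(basename(fa), length(dataset$sequences[[cl]]))
    cm <- dataset$counts[[cl]]
    df <- data.frame(feature_id = cm$feature_ids, cm$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    tsv <- file.path(out_dir, paste0(tolower(cl), "_counts.tsv"))
    write_tsv_commented(df, tsv, prov)
    note(basename(tsv), nrow(df))
  }
  write_tsv_commented(dataset$sample_map,
                      file.path(out_dir, "sample_map.tsv"), prov)
  note("sample_map.tsv", nrow(dataset$sample_map))
  tot <- data.frame(sample_id = names(dataset$mapped_totals),
                    mapped_total = unname(dataset$mapped_totals))
  write_tsv_commented(tot, file.path(out_dir, "mapped_totals.tsv"), prov)
  note("mapped_totals.tsv", nrow(tot))
  write_tsv_commented(dataset$truth$de_effects,
                      file.path(out_dir, "truth_effects.tsv"), prov)
  note("truth_effects.tsv", nrow(dataset$truth$de_effects))
  write_tsv_commented(dataset$truth$triads,
                      file.path(out_dir, "truth_triads.tsv"), prov)
  note("truth_triads.tsv", nrow(dataset$truth$triads))
  write_tsv_commented(dataset$truth$site_plants,
                      file.path(out_dir, "truth_site_plants.tsv"), prov)
  note("truth_site_plants.tsv", nrow(dataset$truth$site_plants))
  jsonlite::write_json(dataset$truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  note("truth.json", nrow(dataset$truth$de_effects))
  do.call(rbind, manifest)
}
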