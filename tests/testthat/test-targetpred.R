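test_that("find_seed_sites reports the let-7 8mer at the expected coordinate", {
  hits <- find_seed_sites(LET7, "AAACUACCUCAAA")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$site_type, "8mer")
  expect_identical(hits$start, 4L)
  expect_identical(hits$end, 12L)
  expect_identical(hits$site_seq, "CUACCUCA")
})

test_that("site types degrade as the m8 match and A1 anchor are removed", {
  # core UACCUC pairs let-7 positions 2-7; flanks control the type
  expect_identical(find_seed_sites(LET7, "GGCUACCUCAGG")$site_type, "8mer")
  expect_identical(find_seed_sites(LET7, "GGCUACCUCGGG")$site_type, "7mer-m8")
  expect_identical(find_seed_sites(LET7, "GGGUACCUCAGG")$site_type, "7mer-A1")
  expect_identical(find_seed_sites(LET7, "GGGUACCUCGGG")$site_type, "6mer")
  expect_identical(nrow(find_seed_sites(LET7, "AAAAAAAAAAAA")), 0L)
})

test_that("alphabet and length preconditions are enforced", {
  expect_error(find_seed_sites("UGAGGUA", "ACGU"), ">= 8")
  expect_error(find_seed_sites(LET7, "ACGTN"), "outside")
  expect_identical(find_seed_sites(LET7, "ACGT")$start, integer(0))
})

test_that("find_seed_sites equals the brute-force oracle on random pairs", {
  set.seed(7)
  for (i in 1:120) {
    mir <- random_rna_string(22)
    topo <- if (i %% 2 == 0) "circular" else "linear"
    tgt <- random_rna_string(sample(60:400, 1))
    got <- find_seed_sites(mir, tgt, topo)
    want <- oracle_seed_scan(mir, tgt, topo)
    expect_identical(got[c("start", "site_type")],
                     want[c("start", "site_type")],
                     info = paste(i, topo))
  }
})

test_that("junction-spanning sites are found only on circular targets", {
  # place the let-7 8mer across the junction: last 4 bases + first 4 bases
  site <- "CUACCUCA"
  tgt <- paste0(substr(site, 5, 8), strrep("G", 40), substr(site, 1, 4))
  circ <- find_seed_sites(LET7, tgt, "circular")
  lin <- find_seed_sites(LET7, tgt, "linear")
  expect_true(any(circ$site_type == "8mer" & circ$start == 45))
  expect_false(any(lin$site_type == "8mer"))
  # circular scanning equals the doubled-sequence scan reduced modulo length
  expect_identical(circ[c("start", "site_type")],
                   oracle_seed_scan(LET7, tgt, "circular")[c("start", "site_type")])
})

test_that("context_score follows the documented additive form", {
  expect_equal(context_score("8mer", 1, TRUE), 100)   # clipped
  expect_equal(context_score("6mer", 0, FALSE), 35)   # below the 50 cutoff
  expect_equal(context_score("7mer-m8", 0.5, FALSE), 70)
  expect_equal(context_score("7mer-A1", 0.25, TRUE), 60)
  # monotone in site-type strength with other features fixed
  scores <- context_score(c("6mer", "7mer-A1", "7mer-m8", "8mer"), 0.3, FALSE)
  expect_true(all(diff(scores) > 0))
  expect_error(context_score("9mer", 0), "site type")
  expect_error(context_score("6mer", 1.2), "au_fraction")
})

test_that("duplex_align scores a perfect duplex and ignores unpairable windows", {
  mir <- "GCGCGCGCGCGAUAUAUAUAUA"  # 11 GC + 11 AU when fully paired
  d <- duplex_align(mir, revcomp_rna(mir))
  expect_equal(d$energy, -(3 * 11 + 2 * 11))
  expect_equal(d$n_wc, 22)
  expect_equal(d$score, 22 * 5)
  nod <- duplex_align("GCGCGCGC", "AAAAAAAAAA")
  expect_equal(nod$score, 0)
  expect_equal(nod$energy, 0)
  expect_error(duplex_align("", "ACGU"), "empty")
  expect_error(duplex_align("ACGU", strrep("A", 100)), "80")
})

test_that("duplex DP equals exhaustive local-alignment enumeration (short strings)", {
  set.seed(11)
  for (i in 1:120) {
    a <- random_rna_string(sample(2:10, 1))
    b <- random_rna_string(sample(2:10, 1))
    expect_equal(duplex_align(a, b)$score, spongenet:::.duplex_brute_cpp(a, b),
                 info = paste(a, b))
  }
})

test_that("duplex energy is internally consistent with its alignment", {
  set.seed(13)
  for (i in 1:40) {
    a <- random_rna_string(22)
    b <- random_rna_string(sample(20:40, 1))
    d <- duplex_align(a, b)
    if (d$score == 0) {
      expect_equal(d$energy, 0)
      next
    }
    aln <- d$alignment
    expect_equal(sum(aln$cls == "WC"), d$n_wc)
    expect_equal(sum(aln$cls == "gap"), d$n_gaps)
    expect_gte(d$n_gaps, d$n_gap_runs)
    # recompute the energy from the alignment columns
    comp <- function(i) {
      pair <- paste0(substr(a, aln$mirna_pos[i], aln$mirna_pos[i]),
                     substr(b, aln$target_pos[i], aln$target_pos[i]))
      if (pair %in% c("GC", "CG")) "GC" else if (pair %in% c("AU", "UA")) "AU"
      else if (pair %in% c("GU", "UG")) "GU" else "MM"
    }
    kinds <- vapply(which(aln$cls != "gap"), comp, character(1))
    e <- -(3 * sum(kinds == "GC") + 2 * sum(kinds == "AU") + sum(kinds == "GU")) +
      4 * d$n_gap_runs + 2 * sum(kinds == "MM")
    expect_equal(d$energy, e)
  }
})

test_that("adding WC pairs to an alignment makes the energy more favourable", {
  # grow a perfect duplex one base at a time: energy strictly decreases
  mir <- "GCAUGCAUGCAUGCAUGCAU"
  energies <- vapply(10:20, function(k) {
    duplex_align(substr(mir, 1, k), revcomp_rna(substr(mir, 1, k)))$energy
  }, numeric(1))
  expect_true(all(diff(energies) < 0))
})

test_that("predict_targets intersects the two scorers under the cutoffs", {
  sim <- small_sim()
  sp <- sim$truth$site_plants
  tr <- sim$truth$triads[1, ]
  mir <- sim$sequences$miRNA[tr$mirna_id]
  tgt <- sim$sequences$mRNA[tr$mrna_id]
  res <- predict_targets(mir, tgt, target_class = "mRNA")
  expect_identical(nrow(res), 1L)
  expect_true(res$passes)
  expect_gte(res$context_score, 50)
  expect_lt(res$energy, -10)
  # tightening either cutoff can only remove pairs
  res2 <- predict_targets(mir, tgt, cutoffs = list(context = 90, energy = -10))
  res3 <- predict_targets(mir, tgt, cutoffs = list(context = 50, energy = -60))
  expect_true(all(res2$passes <= res$passes))
  expect_true(all(res3$passes <= res$passes))
  # no seed site anywhere: the pair is absent entirely
  none <- predict_targets(c(m = "GGGGGGGGGGGGGGGGGGGGGG"),
                          c(t = strrep("G", 100)))
  expect_identical(nrow(none), 0L)
})

test_that("every planted site is recovered by predict_targets at the cutoffs", {
  sim <- small_sim()
  sp <- sim$truth$site_plants
  for (i in seq_len(nrow(sp))) {
    topo <- if (sp$target_class[i] == "circRNA") "circular" else "linear"
    res <- predict_targets(sim$sequences$miRNA[sp$mirna_id[i]],
                           sim$sequences[[sp$target_class[i]]][sp$target_id[i]],
                           target_class = sp$target_class[i], topology = topo)
    expect_true(nrow(res) >= 1 && any(res$passes), info = paste("plant", i))
  }
})
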