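# Independent oracles used to check the implementation. Each one is written
# in the most transparent form available (explicit enumeration, counting
# loops) and never calls the code path it verifies.

# Two-sided Fisher p by explicit table enumeration: all tables with the
# observed margins, probability via products of binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  as_vals <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(as_vals, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  obs <- probs[match(a, as_vals)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Brute-force seed-site scan: slide an explicit window over the target and
# compare against the reverse complement of the relevant miRNA positions.
oracle_seed_scan <- function(mirna, target, topology = "linear") {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }
  L <- nchar(target)
  doubled <- if (topology == "circular") paste0(target, target) else target
  core <- rc(substr(mirna, 2, 7))          # pairs positions 2-7
  m8c <- chartr("ACGU", "UGCA", substr(mirna, 8, 8))
  found <- list()
  for (s in 1:L) {                          # s = core start on the target
    if (s + 5 > nchar(doubled)) next
    if (substr(doubled, s, s + 5) != core) next
    p8 <- s - 1
    if (topology == "circular" && p8 == 0) p8 <- L
    has_m8 <- p8 >= 1 && substr(doubled, p8, p8) == m8c
    pa <- s + 6
    has_a1 <- pa <= nchar(doubled) && substr(doubled, pa, pa) == "A" &&
      (topology == "circular" || pa <= L)
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    st <- if (type %in% c("8mer", "7mer-m8")) s - 1 else s
    if (st < 1) st <- st + L
    if (topology == "circular" && st > L) st <- st - L
    found[[length(found) + 1L]] <- data.frame(start = as.integer(st),
                                              site_type = type,
                                              stringsAsFactors = FALSE)
  }
  if (!length(found)) {
    return(data.frame(start = integer(0), site_type = character(0)))
  }
  out <- unique(do.call(rbind, found))
  out[order(out$start), , drop = FALSE]
}

# Brute-force triad enumeration: triple loop over all (sponge edge,
# mRNA edge) combinations.
oracle_triads <- function(edges) {
  n <- 0L
  keys <- character(0)
  sp <- edges[edges$partner_class %in% c("lncRNA", "circRNA"), , drop = FALSE]
  mr <- edges[edges$partner_class == "mRNA", , drop = FALSE]
  if (nrow(sp) && nrow(mr)) {
    for (i in seq_len(nrow(sp))) for (j in seq_len(nrow(mr))) {
      if (sp$mirna_id[i] == mr$mirna_id[j] &&
          sp$partner_direction[i] == mr$partner_direction[j]) {
        keys <- c(keys, paste(sp$partner_id[i], sp$mirna_id[i], mr$partner_id[j]))
      }
    }
  }
  unique(keys)
}

# Brute-force quad enumeration over all (lncRNA triad, circRNA triad) pairs.
oracle_quads <- function(triads, share_mrna = TRUE) {
  lnc <- triads[triads$sponge_class == "lncRNA", , drop = FALSE]
  circ <- triads[triads$sponge_class == "circRNA", , drop = FALSE]
  keys <- character(0)
  if (nrow(lnc) && nrow(circ)) {
    for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(circ))) {
      ok <- lnc$mirna_id[i] == circ$mirna_id[j] &&
        (!share_mrna || lnc$mrna_id[i] == circ$mrna_id[j])
      if (ok) {
        keys <- c(keys, paste(lnc$sponge_id[i], circ$sponge_id[j],
                              lnc$mirna_id[i], lnc$mrna_id[i]))
      }
    }
  }
  unique(keys)
}

random_edge_table <- function(n_mirna = 5, n_lnc = 5, n_circ = 5, n_mrna = 8,
                              p_edge = 0.3) {
  mk <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  mirs <- mk("mir", n_mirna)
  partners <- data.frame(
    id = c(mk("lnc", n_lnc), mk("circ", n_circ), mk("gene", n_mrna)),
    class = rep(c("lncRNA", "circRNA", "mRNA"), c(n_lnc, n_circ, n_mrna)),
    stringsAsFactors = FALSE)
  mir_dir <- setNames(sample(c("up", "down"), n_mirna, TRUE), mirs)
  partner_dir <- setNames(sample(c("up", "down"), nrow(partners), TRUE),
                          partners$id)
  rows <- list()
  for (m in mirs) for (i in seq_len(nrow(partners))) {
    # edges only exist where directions anticorrelate (as build_edges enforces)
    if (mir_dir[[m]] == partner_dir[[partners$id[i]]]) next
    if (runif(1) < p_edge) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, mirna_direction = mir_dir[[m]],
        partner_id = partners$id[i], partner_class = partners$class[i],
        partner_direction = partner_dir[[partners$id[i]]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), mirna_direction = character(0),
                      partner_id = character(0), partner_class = character(0),
                      partner_direction = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

random_rna_string <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

triad_key <- function(df) {
  if ("sponge_id" %in% names(df)) paste(df$sponge_id, df$mirna_id, df$mrna_id)
  else character(0)
}
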