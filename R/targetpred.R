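comp_base <- function(b) chartr("ACGU", "UGCA", b)

check_rna_alphabet <- function(x, what) {
  x <- toupper(chartr("Tt", "Uu", x))
  if (any(grepl("[^ACGU]", x))) {
    stop_domain(what, " contains characters outside {A,C,G,U/T}")
  }
  x
}

site_type_levels <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Find canonical miRNA seed sites on a target
#'
#' Scans the target (5'->3') for reverse complements of the miRNA seed
#' (positions 2-7) and classifies each occurrence with its strongest
#' canonical type: `8mer` (positions 2-8 paired plus an A opposite position
#' 1) > `7mer-m8` (2-8 paired) > `7mer-A1` (2-7 paired plus the A1) >
#' `6mer` (2-7 paired). Circular targets are scanned with the first 7 bases
#' appended so junction-spanning sites are found; starts are reported modulo
#' the target length (so `end` may exceed it for a wrapped site).
#'
#' @param mirna_seq miRNA sequence, 5'->3', length >= 8.
#' @param target_seq Target sequence, 5'->3'.
#' @param topology `"linear"` or `"circular"`.
#' @param mirna_id,target_id Optional ids copied into the result.
#' @return `data.frame` with columns `mirna_id`, `target_id`, `start`, `end`
#'   (1-based, half-open), `site_type`, `site_seq`.
#' @export
find_seed_sites <- function(mirna_seq, target_seq, topology = c("linear", "circular"),
                            mirna_id = NA_character_, target_id = NA_character_) {
  topology <- match.arg(topology)
  mirna_seq <- check_rna_alphabet(mirna_seq, "miRNA sequence")
  target_seq <- check_rna_alphabet(target_seq, "target sequence")
  if (nchar(mirna_seq) < 8L) stop_domain("miRNA must be >= 8 nt")
  L <- nchar(target_seq)
  empty <- data.frame(mirna_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), site_seq = character(0),
                      stringsAsFactors = FALSE)
  if (L < 6L) return(empty)
  circular <- topology == "circular"
  ext <- if (circular) paste0(target_seq, substr(target_seq, 1L, 7L)) else target_seq
  core6 <- revcomp_rna(substr(mirna_seq, 2L, 7L))
  m8c <- comp_base(substr(mirna_seq, 8L, 8L))

  # manual scan: fixed-pattern gregexpr would skip overlapping occurrences
  starts <- integer(0)
  s <- 1L
  while (s + 5L <= nchar(ext)) {
    hit <- regexpr(core6, substr(ext, s, nchar(ext)), fixed = TRUE)
    if (hit == -1L) break
    pos <- s + as.integer(hit) - 1L
    starts <- c(starts, pos)
    s <- pos + 1L
  }
  starts <- starts[starts <= L]  # avoid duplicating wrapped cores
  if (!length(starts)) return(empty)

  ext_at <- function(pos) {
    if (pos >= 1L && pos <= nchar(ext)) substr(ext, pos, pos) else NA_character_
  }
  rows <- lapply(starts, function(s0) {
    # m8 pairs immediately 5' of the core on the target; A1 sits 3' of it
    m8_pos <- s0 - 1L
    if (circular && m8_pos == 0L) m8_pos <- L
    has_m8 <- m8_pos >= 1L && identical(ext_at(m8_pos), m8c)
    a1_pos <- s0 + 6L
    has_a1 <- if (circular) identical(ext_at(a1_pos), "A") else
      a1_pos <= L && identical(ext_at(a1_pos), "A")
    if (has_m8 && has_a1) {
      type <- "8mer"; st <- s0 - 1L; len <- 8L
    } else if (has_m8) {
      type <- "7mer-m8"; st <- s0 - 1L; len <- 7L
    } else if (has_a1) {
      type <- "7mer-A1"; st <- s0; len <- 7L
    } else {
      type <- "6mer"; st <- s0; len <- 6L
    }
    if (st < 1L) {
      if (!circular) return(NULL)           # unreachable: has_m8 implies st>=1
      st <- st + L
    }
    seq_at <- function(a, b) {
      if (b <= nchar(ext)) substr(ext, a, b)
      else paste0(substr(ext, a, nchar(ext)),
                  substr(target_seq, 1L, b - nchar(ext)))
    }
    site_seq <- if (st + len - 1L <= nchar(ext)) substr(ext, st, st + len - 1L)
      else seq_at(st, st + len - 1L)
    if (circular && st > L) st <- st - L
    data.frame(mirna_id = mirna_id, target_id = target_id,
               start = st, end = st + len, site_type = type,
               site_seq = site_seq, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("start", "site_type")]), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Context-style site score on a 0-100 scale
#'
#' A simplified analogue of context scoring: a base score per site type
#' (8mer 75, 7mer-m8 60, 7mer-A1 50, 6mer 35), plus `20 * AU fraction` of the
#' 30-nt flanks, plus 5 when the site lies within 15 nt of either target end
#' (linear targets only) without overlapping it; clipped to [0, 100].
#'
#' @param site_type One of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @param au_fraction AU fraction of the flanking sequence, in [0, 1].
#' @param near_end Logical: site within 15 nt of an end.
#' @return Score in [0, 100]. Vectorised.
#' @export
context_score <- function(site_type, au_fraction, near_end = FALSE) {
  base <- c(`6mer` = 35, `7mer-A1` = 50, `7mer-m8` = 60, `8mer` = 75)
  if (!all(site_type %in% names(base))) stop_domain("unknown site type")
  if (any(au_fraction < 0) || any(au_fraction > 1)) {
    stop_domain("au_fraction must lie in [0, 1]")
  }
  pmin(100, pmax(0, base[site_type] + 20 * au_fraction + 5 * as.numeric(near_end)))
}

# AU fraction of the 30-nt flanks on each side of a site, and the near-end
# bonus predicate, computed from the target sequence.
site_context_features <- function(target_seq, start, end, topology) {
  L <- nchar(target_seq)
  circular <- topology == "circular"
  grab <- function(a, b) {
    if (a > b) return("")
    if (!circular) {
      a <- max(1L, a); b <- min(L, b)
      if (a > b) return("")
      return(substr(target_seq, a, b))
    }
    idx <- ((seq(a, b) - 1L) %% L) + 1L
    paste(strsplit(target_seq, "")[[1]][idx], collapse = "")
  }
  flank <- paste0(grab(start - 30L, start - 1L), grab(end, end + 29L))
  au <- if (nchar(flank) == 0) 0 else {
    sum(strsplit(flank, "")[[1]] %in% c("A", "U")) / nchar(flank)
  }
  near <- FALSE
  if (!circular) {
    dist <- min(start - 1L, L - (end - 1L))
    near <- dist >= 1L && dist <= 15L
  }
  list(au_fraction = au, near_end = near)
}

#' Align a miRNA against a target window (duplex formation)
#'
#' Local alignment of the miRNA (5'->3') against the reversed window by
#' dynamic programming with complementarity scoring (Watson-Crick +5, G:U
#' +2, mismatch -3, doubled in the seed region, gap open -8 / extend -2) and
#' an additive energy for the optimal alignment:
#' `-(3 GC + 2 AU + 1 GU) + 4 gap openings + 2 internal mismatches` kcal/mol
#' (a gap run counts once, as a single indel event).
#' A best score <= 0 means no duplex: score 0, energy 0.
#'
#' @param mirna_seq miRNA sequence.
#' @param target_window Target window, <= 80 nt.
#' @return List with `score`, `energy`, pair counts, and the `alignment`
#'   data.frame (mirna_pos, target_pos, cls in {WC, GU, mismatch, gap}).
#' @export
duplex_align <- function(mirna_seq, target_window) {
  mirna_seq <- check_rna_alphabet(mirna_seq, "miRNA sequence")
  target_window <- check_rna_alphabet(target_window, "target window")
  if (!nzchar(mirna_seq) || !nzchar(target_window)) {
    stop_domain("duplex_align: empty sequence")
  }
  if (nchar(target_window) > 80L) stop_domain("target window must be <= 80 nt")
  .duplex_align_cpp(mirna_seq, target_window)
}

# Window around a site used for duplex scoring: the site plus enough 5'
# target sequence for the miRNA 3' end to pair, and a short 3' flank.
duplex_window <- function(target_seq, start, end, mirna_len, topology) {
  L <- nchar(target_seq)
  a <- start - (mirna_len - (end - start)) - 4L
  b <- end + 3L
  if (topology == "circular") {
    idx <- ((seq(a, b) - 1L) %% L) + 1L
    paste(strsplit(target_seq, "")[[1]][idx], collapse = "")
  } else {
    substr(target_seq, max(1L, a), min(L, b))
  }
}

#' Predict miRNA-target pairs by seed scan + duplex energy intersection
#'
#' For every (miRNA, target) pair with at least one canonical seed site, the
#' best site is the one with the maximal context score (ties to the smallest
#' start) and the best duplex is the minimum energy over windows centred on
#' the sites. A pair passes the intersection filter when
#' `context_score >= cutoffs$context` AND `energy < cutoffs$energy` — the
#' analogue of keeping predictions shared by both programs.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param targets Named character vector of target sequences.
#' @param target_class Class of the targets (`mRNA`, `lncRNA`, `circRNA`).
#' @param topology `"linear"` or `"circular"` (recycled over targets).
#' @param cutoffs List with `context` (default 50) and `energy`
#'   (default -10).
#' @return `data.frame`: one row per pair with a site — `mirna_id`,
#'   `target_id`, `class`, `site_type`, `start`, `end`, `context_score`,
#'   `energy`, `passes`.
#' @export
predict_targets <- function(mirnas, targets, target_class = "mRNA",
                            topology = "linear",
                            cutoffs = list(context = 50, energy = -10)) {
  target_class <- match.arg(target_class, TARGET_CLASSES)
  if (!all(is.finite(c(cutoffs$context, cutoffs$energy)))) {
    stop_domain("cutoffs must be finite")
  }
  topology <- rep_len(topology, length(targets))
  rows <- list()
  for (mi in seq_along(mirnas)) {
    m_id <- names(mirnas)[mi]; m_seq <- mirnas[[mi]]
    for (ti in seq_along(targets)) {
      t_id <- names(targets)[ti]; t_seq <- targets[[ti]]; topo <- topology[ti]
      sites <- find_seed_sites(m_seq, t_seq, topo, m_id, t_id)
      if (!nrow(sites)) next
      feats <- lapply(seq_len(nrow(sites)), function(i) {
        site_context_features(t_seq, sites$start[i], sites$end[i], topo)
      })
      cs <- vapply(seq_len(nrow(sites)), function(i) {
        context_score(sites$site_type[i], feats[[i]]$au_fraction,
                      feats[[i]]$near_end)
      }, numeric(1))
      energies <- vapply(seq_len(nrow(sites)), function(i) {
        win <- duplex_window(t_seq, sites$start[i], sites$end[i],
                             nchar(m_seq), topo)
        duplex_align(m_seq, win)$energy
      }, numeric(1))
      best <- order(-cs, sites$start)[1]
      e_min <- min(energies)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m_id, target_id = t_id, class = target_class,
        site_type = sites$site_type[best], start = sites$start[best],
        end = sites$end[best], context_score = cs[best], energy = e_min,
        passes = cs[best] >= cutoffs$context & e_min < cutoffs$energy,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      class = character(0), site_type = character(0),
                      start = integer(0), end = integer(0),
                      context_score = numeric(0), energy = numeric(0),
                      passes = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
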