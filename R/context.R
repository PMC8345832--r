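# Simulation context: integer-coded lookup tables precomputed once per
# (haplotype table, serology map, eplet table) triple. Genotypes are
# haplotype-index pairs, antigens and eplets are integer codes, so the daily
# allocation loop runs on plain vector arithmetic. The scalar S3 API
# (mismatch_grade(), eplet_mismatch(), epitope_score()) is the reference
# semantics; property tests assert the two paths agree.

#' Build a simulation context
#'
#' Precomputes per-haplotype serologic codes (A/B broad, DR split), full
#' antigen code sets for the virtual crossmatch, the haplotype-by-eplet
#' incidence matrix driving the surrogate scorer, the eplet-to-antigen
#' translation used for sensitization, and the reference genotype panel for
#' the mismatch-probability components.
#'
#' @param haplotypes a [haplotype_table()].
#' @param serology a [serology_map()] resolving every allele in the table.
#' @param eplets an [eplet_table()].
#' @param scorer an `epitope_scorer`; defaults to the eplet-load surrogate.
#' @param panel_k number of top haplotypes forming the reference panel
#'   (clipped to the table size).
#' @return a `sim_context`.
#' @export
sim_context <- function(haplotypes, serology, eplets,
                        scorer = surrogate_scorer(eplets), panel_k = 49) {
  stopifnot(inherits(haplotypes, "haplotype_table"),
            inherits(serology, "serology_map"),
            inherits(eplets, "eplet_table"))
  H <- nrow(haplotypes)
  st <- serology$table
  ag_names <- sort(unique(c(paste(st$locus, st$broad, sep = "|"),
                            paste(st$locus, st$split, sep = "|"))))
  ag_code <- seq_along(ag_names)
  names(ag_code) <- ag_names

  res_col <- function(locus, field) {
    al <- haplotypes[[locus]]
    vapply(al, function(a) .resolve_allele(serology, locus, a)[[field]],
           character(1), USE.NAMES = FALSE)
  }
  hA <- unname(ag_code[paste("A", res_col("A", "broad"), sep = "|")])
  hB <- unname(ag_code[paste("B", res_col("B", "broad"), sep = "|")])
  hDR <- unname(ag_code[paste("DRB1", res_col("DRB1", "split"), sep = "|")])

  # all broad+split antigen codes displayed by each haplotype, over every
  # locus the serology map covers (used by the virtual crossmatch)
  hap_ags <- vector("list", H)
  for (i in seq_len(H)) {
    ags <- character(0)
    for (l in hla_loci()) {
      v <- get0(paste(l, haplotypes[[l]][i], sep = "|"),
                envir = serology$lookup, inherits = FALSE)
      if (!is.null(v))
        ags <- c(ags, paste(l, v[["broad"]], sep = "|"),
                 paste(l, v[["split"]], sep = "|"))
    }
    hap_ags[[i]] <- unname(sort(unique(ag_code[ags])))
  }

  M <- hap_eplet_incidence(haplotypes, eplets)
  w <- if (identical(scorer$kind, "surrogate")) scorer$weights else eplets$weights
  w <- unname(w[colnames(M)])

  # eplet index -> antigen codes of all alleles carrying it
  inc <- eplets$incidence
  ep_ags <- lapply(eplets$eplets, function(e) {
    al <- inc$allele[inc$eplet == e]
    hit <- st[st$allele %in% al, , drop = FALSE]
    unname(sort(unique(ag_code[c(paste(hit$locus, hit$broad, sep = "|"),
                                 paste(hit$locus, hit$split, sep = "|"))])))
  })

  panel <- build_genotype_panel(haplotypes, min(panel_k, H))
  p1 <- panel$haps[, 1L]; p2 <- panel$haps[, 2L]
  panel_codes <- list(
    a1 = hA[p1], a2 = hA[p2], b1 = hB[p1], b2 = hB[p2],
    dr1 = hDR[p1], dr2 = hDR[p2],
    M = M[p1, , drop = FALSE] | M[p2, , drop = FALSE])

  structure(list(
    haplotypes = haplotypes, serology = serology, eplets = eplets,
    scorer = scorer, H = H,
    ag_code = ag_code, n_ags = length(ag_code),
    hA = hA, hB = hB, hDR = hDR, hap_ags = hap_ags,
    M = M, w = w, ep_ags = ep_ags,
    panel = panel, panel_codes = panel_codes,
    pfav_cache = new.env(parent = emptyenv()),
    rp_cache = new.env(parent = emptyenv())
  ), class = "sim_context")
}

#' @export
print.sim_context <- function(x, ...) {
  cat(sprintf(paste0("Simulation context: %d haplotypes, %d antigens, ",
                     "%d eplets, panel of %d genotypes, scorer '%s'\n"),
              x$H, x$n_ags, ncol(x$M), panel_size(x$panel), x$scorer$name))
  invisible(x)
}

# internal: per-locus mismatch count, vectorized over candidates.
# d1,d2 scalars (donor antigen codes); r1,r2 vectors (recipient codes).
.mm_locus <- function(d1, d2, r1, r2) {
  (d1 != r1 & d1 != r2) + ((d2 != d1) & (d2 != r1 & d2 != r2))
}

# internal: surrogate scores of one donor against candidate eplet rows.
# dvec: donor eplet logical vector; R: candidates x eplets logical matrix.
# score_i = sum_e w_e d_e (1 - r_ie) = sum(w d) - R_i . (w d)
.surrogate_scores <- function(dvec, R, w) {
  wd <- w * dvec
  total <- sum(wd)
  s <- as.numeric(total - R %*% wd)
  s[s < 1e-9] <- 0  # cancellation dust when the recipient covers the donor
  s
}

# internal: cached p_favorable for a genotype given by haplotype indices
.pfav_hap <- function(ctx, h1, h2) {
  key <- paste0(h1, ":", h2)
  v <- get0(key, envir = ctx$pfav_cache, inherits = FALSE)
  if (!is.null(v)) return(v)
  # panel genotypes act as donors (donor-relative mismatch count)
  pf <- sum(ctx$panel$freq[.panel_mm_vs_patient(ctx, h1, h2) <= 1L])
  assign(key, pf, envir = ctx$pfav_cache)
  pf
}

# internal: total mismatch grade of every panel genotype (as donor) against
# the patient (h1,h2)
.panel_mm_vs_patient <- function(ctx, h1, h2) {
  pc <- ctx$panel_codes
  .mm_locus_sw(pc$a1, pc$a2, ctx$hA[h1], ctx$hA[h2]) +
    .mm_locus_sw(pc$b1, pc$b2, ctx$hB[h1], ctx$hB[h2]) +
    .mm_locus_sw(pc$dr1, pc$dr2, ctx$hDR[h1], ctx$hDR[h2])
}

# vectorized over donors (d1,d2 vectors), scalar recipient (r1,r2)
.mm_locus_sw <- function(d1, d2, r1, r2) {
  (d1 != r1 & d1 != r2) + ((d2 != d1) & (d2 != r1 & d2 != r2))
}

# internal: cached risk-profile weighted median for genotype (h1,h2):
# panel genotypes as virtual donors scored against the patient
.rp_hap <- function(ctx, h1, h2) {
  key <- paste0(h1, ":", h2)
  v <- get0(key, envir = ctx$rp_cache, inherits = FALSE)
  if (!is.null(v)) return(v)
  pvec <- ctx$M[h1, ] | ctx$M[h2, ]
  # score of panel donor i vs patient = sum_e w_e D_ie (1 - p_e)
  scores <- as.numeric(ctx$panel_codes$M %*% (ctx$w * !pvec))
  rp <- weighted_median_lower(scores, ctx$panel$freq)
  assign(key, rp, envir = ctx$rp_cache)
  rp
}
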