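#' Pairwise linkage disequilibrium r-squared from unphased genotypes
#'
#' Estimates the two-locus haplotype frequencies from unphased dosage
#' vectors by expectation-maximization (only the double heterozygote is
#' phase-ambiguous; it is split between the two phase configurations in
#' proportion to their current expected frequencies), then returns
#' `r^2 = D^2 / (p_A p_a p_B p_b)` where `D` is the gametic disequilibrium
#' of the estimated haplotype frequencies.
#'
#' EM starts at linkage equilibrium and runs until the largest haplotype
#' frequency change is below `tol` or `max_iter` iterations.
#'
#' @param g1,g2 Integer dosage vectors 0/1/2 over the same samples; `NA`
#'   allowed (pairwise-complete cases are used).
#' @param max_iter,tol EM stopping rule (defaults 100 and 1e-8).
#' @return `r^2` in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2, max_iter = 100, tol = 1e-8) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2) stop("fewer than 2 pairwise-complete samples")
  p1 <- sum(g1) / (2 * n)
  p2 <- sum(g2) / (2 * n)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    stop("monomorphic marker among shared samples: r^2 undefined")
  }
  # 3x3 genotype table; haplotypes over alleles (a = counted at locus 1,
  # A = other; b = counted at locus 2, B = other): h = (ab, aB, Ab, AB)
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  h <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  names(h) <- c("ab", "aB", "Ab", "AB")
  # unambiguous decomposition: for every genotype cell except the double
  # heterozygote the two haplotypes are determined — at least one locus is
  # homozygous, so the pairing of its alleles with the other locus' is
  # forced (or arbitrary-but-equivalent)
  unamb <- matrix(0, 9, 4,
                  dimnames = list(NULL, c("ab", "aB", "Ab", "AB")))
  k <- 1
  for (i in 0:2) for (j in 0:2) {
    if (!(i == 1 && j == 1)) {
      a_alleles <- c(rep("a", i), rep("A", 2 - i))
      b_alleles <- c(rep("b", j), rep("B", 2 - j))
      haps <- paste0(a_alleles, b_alleles)
      for (hp in haps) unamb[k, hp] <- unamb[k, hp] + 1
    }
    k <- k + 1
  }
  n11 <- tab[2, 2]
  base_cnt <- as.vector(t(unamb) %*% as.vector(t(tab)))
  names(base_cnt) <- c("ab", "aB", "Ab", "AB")

  for (it in seq_len(max_iter)) {
    denom <- h["ab"] * h["AB"] + h["aB"] * h["Ab"]
    split11 <- if (denom > 0) h["ab"] * h["AB"] / denom else 0.5
    cnt <- base_cnt + n11 * c(split11, 1 - split11, 1 - split11, split11)
    h_new <- cnt / (2 * n)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  d <- h["ab"] - (h["ab"] + h["aB"]) * (h["ab"] + h["Ab"])
  pa <- h["ab"] + h["aB"]; pb <- h["ab"] + h["Ab"]
  unname(d^2 / (pa * (1 - pa) * pb * (1 - pb)))
}
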