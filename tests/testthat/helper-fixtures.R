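# Fixture pedigrees and independent oracles shared across test files.
# All oracles here are deliberately naive (enumeration / path counting),
# independent of the package's algorithms.

# Minimal 12-member second-cousin pedigree: GG1 x GG2 -> U1, U2; each
# marries in (S1, S2); grandchildren P1, P2 marry in (Q1, Q2); A and B
# are second cousins sharing only the great-grandparental couple.
second_cousin_pedigree <- function() {
  pedigree(
    id        = c("GG1", "GG2", "U1", "U2", "S1", "S2",
                  "P1", "P2", "Q1", "Q2", "A", "B"),
    father_id = c(NA, NA, "GG1", "GG1", NA, NA,
                  "U1", "U2", NA, NA, "P1", "P2"),
    mother_id = c(NA, NA, "GG2", "GG2", NA, NA,
                  "S1", "S2", NA, NA, "Q1", "Q2"),
    sex = c("male", "female", "male", "male", "female", "female",
            "male", "male", "female", "female", "male", "female"))
}

sib_pedigree <- function() {
  pedigree(id = c("f", "m", "s1", "s2"),
           father_id = c(NA, NA, "f", "f"),
           mother_id = c(NA, NA, "m", "m"))
}

# --- path-counting kinship oracle ----------------------------------------

.ancestor_paths <- function(ped, x) {
  father <- stats::setNames(ped$father_id, ped$id)
  mother <- stats::setNames(ped$mother_id, ped$id)
  res <- list()
  walk <- function(path) {
    res[[length(res) + 1L]] <<- path
    for (p in c(father[[path[length(path)]]], mother[[path[length(path)]]]))
      if (!is.na(p)) walk(c(path, p))
  }
  walk(x)
  res
}

# phi(a, b) as the sum over common ancestors X and node-disjoint path
# pairs of (1/2)^(links_a + links_b + 1) * (1 + F_X).
phi_path_oracle <- function(ped, a, b) {
  fa <- ped$father_id[ped$id == a]
  ma <- ped$mother_id[ped$id == a]
  if (a == b) {
    if (is.na(fa)) return(0.5)
    return(0.5 * (1 + phi_path_oracle(ped, fa, ma)))
  }
  pa <- .ancestor_paths(ped, a)
  pb <- .ancestor_paths(ped, b)
  tot <- 0
  for (P in pa) for (Q in pb) {
    X <- P[length(P)]
    if (X != Q[length(Q)]) next
    if (length(intersect(P[-length(P)], Q[-length(Q)]))) next
    fX <- ped$father_id[ped$id == X]
    FX <- if (is.na(fX)) 0 else
      phi_path_oracle(ped, fX, ped$mother_id[ped$id == X])
    tot <- tot + 0.5^(length(P) + length(Q) - 1) * (1 + FX)
  }
  tot
}

# --- variant-table builders ----------------------------------------------

make_vt <- function(geno, consequence = NULL, gene = NULL,
                    dbsnp_id = NULL, maf = NULL) {
  n <- nrow(geno)
  sites <- data.frame(
    chrom = rep("1", n), pos = seq_len(n) * 100L,
    ref = rep("A", n), alt = rep("G", n),
    consequence = if (is.null(consequence)) rep("missense", n) else consequence,
    gene = if (is.null(gene)) sprintf("G%03d", seq_len(n)) else gene,
    dbsnp_id = if (is.null(dbsnp_id)) rep(NA_character_, n) else dbsnp_id,
    maf = if (is.null(maf)) rep(NA_real_, n) else maf,
    stringsAsFactors = FALSE)
  coding <- sites$consequence %in% c("missense", "synonymous", "nonsense")
  sites$gene[!coding & is.null(gene)] <- NA
  variant_table(sites, geno)
}

random_vt <- function(n_var, samples, seed) {
  set.seed(seed)
  geno <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                        n_var * length(samples), replace = TRUE,
                        prob = c(0.55, 0.3, 0.05, 0.1)),
                 nrow = n_var, dimnames = list(NULL, samples))
  cons <- sample(c("missense", "synonymous", "nonsense", "splice_site",
                   "utr", "intronic", "intergenic"), n_var, replace = TRUE)
  has_rs <- runif(n_var) < 0.6
  maf <- ifelse(runif(n_var) < 0.7, runif(n_var, 0, 0.5), NA)
  make_vt(geno, consequence = cons,
          dbsnp_id = ifelse(has_rs, sprintf("rs%06d", seq_len(n_var)), NA),
          maf = maf)
}

# Brute-force truth-table filter oracle: keep a variant iff every
# affected sample carries an alt allele and no unaffected sample does
# (missing fails sharing in affected, is ignored in unaffected).
filter_oracle_keep <- function(geno_row, affected, unaffected) {
  carries <- function(g) g %in% c("het", "hom_alt")
  all(vapply(geno_row[affected], carries, logical(1))) &&
    !any(vapply(geno_row[unaffected], carries, logical(1)))
}

# --- statistical oracles --------------------------------------------------

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by exhaustive arrangement enumeration.
mw_oracle <- function(x, y) {
  nx <- length(x); pooled <- c(x, y)
  u_of <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  us <- apply(utils::combn(length(pooled), nx), 2, u_of)
  p_lo <- mean(us <= u_obs); p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Hand evaluation of the log-rank O-E sum and hypergeometric variance.
logrank_oracle <- function(g1, g2) {
  time <- c(g1$time, g2$time); event <- c(g1$event, g2$event)
  grp1 <- rep(c(TRUE, FALSE), c(nrow(g1), nrow(g2)))
  oe <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp1)
    d <- sum(event & time == t); d1 <- sum(event & time == t & grp1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- oe^2 / v
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# A CDS long enough to place an arginine codon at position 268, with the
# substitutable C as the first base of that codon (CDS position 802).
long_toy_cds <- function() {
  codons <- c("ATG", rep("GGC", 266), "CGC", "TAA")
  paste(codons, collapse = "")
}

toy_transcripts <- function() {
  read_transcript_models(
    system.file("extdata", "toy_transcripts.tsv", package = "famvarscan"),
    system.file("extdata", "toy_transcripts.fa", package = "famvarscan"))
}
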