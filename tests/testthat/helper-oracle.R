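# Independent arithmetic oracle used to compute expected values for the
# derived examples and property tests.  It sums isotope masses directly
# from literal constants and never calls the package's formula machinery,
# so agreement between the two routes is a real check.

orc <- local({
  mH <- 1.00782503207; mC <- 12; mN <- 14.00307400446
  mO <- 15.99491461957; mP <- 30.97376199842; mS <- 31.97207117441
  mPt <- 194.96479170
  mp <- 1.00727646688; me <- 0.00054857990
  H2O <- 2 * mH + mO; HPO3 <- mH + mP + 3 * mO
  nuc <- c(A = 10 * mC + 13 * mH + 5 * mN + 3 * mO,
           C = 9 * mC + 13 * mH + 3 * mN + 4 * mO,
           G = 10 * mC + 13 * mH + 5 * mN + 4 * mO,
           T = 10 * mC + 14 * mH + 2 * mN + 5 * mO)
  base <- c(A = 5 * mC + 5 * mH + 5 * mN,
            C = 4 * mC + 5 * mH + 3 * mN + mO,
            G = 5 * mC + 5 * mH + 5 * mN + mO,
            T = 5 * mC + 6 * mH + 2 * mN + 2 * mO)
  res <- c(G = 2 * mC + 3 * mH + mN + mO, A = 3 * mC + 5 * mH + mN + mO,
           S = 3 * mC + 5 * mH + mN + 2 * mO, P = 5 * mC + 7 * mH + mN + mO,
           V = 5 * mC + 9 * mH + mN + mO, T = 4 * mC + 7 * mH + mN + 2 * mO,
           C = 3 * mC + 5 * mH + mN + mO + mS, L = 6 * mC + 11 * mH + mN + mO,
           I = 6 * mC + 11 * mH + mN + mO, N = 4 * mC + 6 * mH + 2 * mN + 2 * mO,
           D = 4 * mC + 5 * mH + mN + 3 * mO, Q = 5 * mC + 8 * mH + 2 * mN + 2 * mO,
           K = 6 * mC + 12 * mH + 2 * mN + mO, E = 5 * mC + 7 * mH + mN + 3 * mO,
           M = 5 * mC + 9 * mH + mN + mO + mS, H = 6 * mC + 7 * mH + 3 * mN + mO,
           F = 9 * mC + 9 * mH + mN + mO, R = 6 * mC + 12 * mH + 4 * mN + mO,
           Y = 9 * mC + 9 * mH + mN + 2 * mO, W = 11 * mC + 10 * mH + 2 * mN + mO)
  list(
    mp = mp, me = me, H2O = H2O, HPO3 = HPO3, link = HPO3 - H2O,
    nuc = nuc, base = base, res = res,
    PtA2 = mPt + 2 * mN + 6 * mH, PtA1 = mPt + mN + 3 * mH, Pt = mPt,
    oligo = function(s) {
      r <- strsplit(s, "")[[1]]
      sum(nuc[r]) + (length(r) - 1) * (HPO3 - H2O)
    },
    piece = function(s, p, q) {
      r <- strsplit(s, "")[[1]][p:q]
      sum(nuc[r]) + (length(r) - 1) * (HPO3 - H2O)
    },
    pep = function(s) sum(res[strsplit(s, "")[[1]]]) + H2O,
    mz = function(M, er, pa, pr, z) (M - er * me + (pa - pr) * mp) / abs(z)
  )
})

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

S1 <- "GTATTGGCACGTA"
S1C <- "TACGTGCCAATAC"
P1 <- "VLEYLTAEILE"
P2 <- "SKAMGIMNSFVNDIFERIAGEASRLAHY"

frag_by_label <- function(frags, lab) {
  out <- frags[frags$label == lab, ]
  stopifnot(nrow(out) == 1L)
  out
}
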