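# Small in-code fixtures shared across test files.

tiny_dataset <- function(values, groups, id = "toy") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_dataset(values, groups, id)
}

# n_feat x (n_norm + n_tum) Gaussian dataset, optionally with planted rows
random_dataset <- function(n_feat = 50, n_norm = 10, n_tum = 10, seed = 1,
                           planted = integer(0), shift = 3,
                           missing = 0) {
  set.seed(seed)
  v <- matrix(rnorm(n_feat * (n_norm + n_tum), 8, 1), n_feat,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_norm + n_tum))))
  groups <- rep(c("normal", "tumor"), c(n_norm, n_tum))
  for (f in planted) {
    act <- sample(which(groups == "tumor"), max(1, round(0.3 * n_tum)))
    v[f, act] <- v[f, act] + shift
  }
  if (missing > 0) v[runif(length(v)) < missing] <- NA
  expression_dataset(v, groups, "rand")
}

small_edge_df <- function() {
  data.frame(
    mirna = c("mA", "mA", "mA", "mB", "mB"),
    gene = c("g1", "g2", "g3", "g3", "g4"),
    source = c("targetscan", "targetscan", "miranda", "pictar", "pictar"),
    stringsAsFactors = FALSE)
}

# the ten printed (hits/size, p) pathway rows used for the relevance screen
screen_fixture <- function() {
  data.frame(
    pathway = c("TGF, WNT and cytoskeletal remodeling", "AKT signaling",
                "Brca1 as a transcription regulator", "PTEN pathway",
                "PIP3 signaling in cardiac myocytes",
                "Regulation of epithelial-to-mesenchymal transition",
                "Influence of Ras and Rho proteins on G1/S Transition",
                "Cytoskeleton remodeling",
                "Regulation of G1/S transition (part 1)",
                "Receptor-mediated HIF regulation"),
    hits = c(25, 17, 13, 15, 15, 16, 14, 18, 11, 11),
    size = c(111, 43, 30, 46, 47, 64, 53, 102, 38, 39),
    p = c(2.41e-16, 5.00e-16, 3.70e-13, 7.79e-13, 1.12e-12, 1.12e-11,
          1.14e-10, 3.30e-10, 7.43e-10, 1.02e-9),
    stringsAsFactors = FALSE)
}
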