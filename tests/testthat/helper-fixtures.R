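# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(10L, 5L, 0L,
                2L, 8L, 4L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("otuA", "otuB", "otuC")))
  m
}

tiny_metadata <- function(sample_ids = c("s1", "s2")) {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             queen_id = paste0("Q", seq_len(n)),
             niche = rep(NICHE_LEVELS, length.out = n),
             age_class = rep(c("young", "old"), length.out = n),
             source = "AZ",
             age_months = rep(c(5, 17), length.out = n),
             stringsAsFactors = FALSE)
}

tiny_table <- function() otu_table(tiny_counts(), tiny_metadata())

# 2x2 cohort labels mirroring the unbalanced study design
study_factors <- function(n = c(16, 16, 15, 16)) {
  data.frame(age_class = rep(c("young", "old", "young", "old"), n),
             source = rep(c("CA", "CA", "AZ", "AZ"), n),
             stringsAsFactors = FALSE)
}

# brute-force two-sided rank-sum p by enumeration of all label splits
enumerate_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(y)) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
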