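# Shared fixture builders; everything is generated in code.

countsFixture <- function() {
  m <- matrix(c(5, 0, 3, 2,
                1, 4, 0, 5,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("t1", "t2", "t3", "t4")))
  communityTable(m, "counts")
}

annotationFixture <- function() {
  data.frame(taxon_id = c("t1", "t2", "t3", "t4"),
             kingdom = "Fungi",
             phylum = c("p1", "p1", "p1", "p2"),
             class = c("c1", "c1", "c1", "c2"),
             order = c("o1", "o1", "o1", "o2"),
             family = c("f1", "f1", "f1", "f2"),
             genus = c("g1", "g1", "g2", "g3"),
             guild = c("yeast", "yeast", "saprotroph", "plant_pathogen"),
             stringsAsFactors = FALSE)
}

metadataFixture <- function(ids = c("s1", "s2", "s3")) {
  data.frame(sample_id = ids,
             compartment = rep_len(c("leaf", "root", "soil"), length(ids)),
             week = rep_len(1:3, length(ids)),
             treatment = "control",
             cultivar = "RTx430",
             plot = rep_len(c("plot1", "plot2"), length(ids)),
             x = 0, y = 0, community_size = 10,
             stringsAsFactors = FALSE)
}

# 20 gradient communities with moving-window support: nearby samples share
# more taxa and are more similar, giving a decreasing DOC.
gradientRelTable <- function(n = 20, window = 20) {
  S <- n + window - 1
  m <- matrix(0, n, S,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("t%02d", seq_len(S))))
  w <- stats::dlnorm(seq_len(window), 1.5, 0.6)
  for (i in seq_len(n)) m[i, i:(i + window - 1)] <- w / sum(w)
  communityTable(m, "relative")
}

# Successional communities (Gaussian temporal niches) plus a treatment
# whose composition is the control profile shifted `shift` weeks younger.
successionFixture <- function(weeks = 1:12, reps = 6, shift = 2, S = 60,
                              depth = 400, seed = 5) {
  set.seed(seed)
  peak <- seq(0, max(weeks) + 1, length.out = S)
  profile <- function(w) {
    lam <- exp(-((w - peak) / 2)^2)
    stats::rmultinom(1, depth, lam / sum(lam))[, 1]
  }
  rows <- list(); md <- list()
  for (w in weeks) for (r in seq_len(reps)) {
    id <- sprintf("C_w%02d_r%d", w, r)
    rows[[id]] <- profile(w)
    md[[id]] <- data.frame(sample_id = id, compartment = "leaf", week = w,
                           treatment = "control")
  }
  for (w in weeks[weeks - shift >= min(weeks) - 1]) for (r in 1:4) {
    id <- sprintf("D_w%02d_r%d", w, r)
    rows[[id]] <- profile(w - shift)
    md[[id]] <- data.frame(sample_id = id, compartment = "leaf", week = w,
                           treatment = "pre_flowering_drought")
  }
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("t%02d", seq_len(S))
  list(table = communityTable(m, "counts"), metadata = do.call(rbind, md))
}
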