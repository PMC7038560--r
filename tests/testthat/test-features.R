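test_that("EIIP features match the definition on degenerate and toy inputs", {
  polyA <- eiip_features(strrep("A", 41))
  expect_equal(unname(polyA["eiip.AAA"]), 0.1260)
  expect_equal(sum(polyA[names(polyA) != "eiip.AAA"]), 0)

  # any sequence lacking a trinucleotide scores 0 there
  noG <- paste0(strrep("AC", 20), "A")
  expect_equal(unname(eiip_features(noG)["eiip.GGG"]), 0)

  # ACGT repeated to 41 nt vs the brute-force counting oracle
  seq <- substr(strrep("ACGT", 11), 1, 41)
  expect_equal(unname(eiip_features(seq)), unname(oracle_eiip(seq)))
  present <- c("eiip.ACG", "eiip.CGT", "eiip.GTA", "eiip.TAC")
  expect_true(all(eiip_features(seq)[present] > 0))
  expect_equal(sum(eiip_features(seq)[setdiff(names(polyA), present)]), 0)

  expect_error(eiip_features("ACGN"), "non-ACGT")
})

test_that("EIIP features are bounded and frequencies sum to one", {
  set.seed(101)
  for (i in 1:20) {
    s <- random_window()
    v <- eiip_features(s)
    expect_true(all(v >= 0 & v <= 0.1340))
    # recover frequencies by dividing out the mean-EIIP factors
    means <- sapply(strsplit(sub("eiip\\.", "", names(v)), ""), function(ch) {
      mean(eiip_table()[ch])
    })
    expect_equal(sum(v / means), 1)
  }
})

test_that("double-strand reduction collapses complementary bases", {
  expect_equal(ds_reduce("TCGAGTGAC"), "ACCACACAC")
  expect_equal(ds_reduce("ACGT"), "ACCA")
  expect_equal(ds_reduce("AAAA"), "AAAA")
  expect_error(ds_reduce("ACGX"), "non-ACGT")
})

test_that("PSTNP fitting reproduces degenerate identities", {
  set.seed(7)
  seqs <- replicate(5, random_window())
  same <- fit_pstnp(seqs, seqs)
  expect_true(all(same$Zss == 0))
  expect_true(all(same$Zds == 0))

  m <- fit_pstnp(strrep("A", 41), strrep("C", 41))
  expect_true(all(m$Zss["AAA", ] == 1))
  expect_true(all(m$Zss["CCC", ] == -1))
  expect_equal(sum(abs(m$Zss)), 2 * 39)
  expect_true(all(m$Zds["AAA", ] == 1))
  expect_true(all(m$Zds["CCC", ] == -1))
})

test_that("PSTNP matrices and encodings match the counting oracle", {
  set.seed(13)
  pos <- replicate(3, random_window())
  neg <- replicate(3, random_window())
  m <- fit_pstnp(pos, neg)
  expect_equal(unname(m$Zss), unname(oracle_pstnp_fit(pos, neg)))
  expect_equal(
    unname(m$Zds),
    unname(oracle_pstnp_fit(sapply(pos, oracle_ds_reduce),
                            sapply(neg, oracle_ds_reduce),
                            alphabet = c("A", "C")))
  )
  q <- random_window()
  expect_equal(unname(pstnp_features(q, m, "ss")),
               oracle_pstnp_encode(q, oracle_pstnp_fit(pos, neg)))
  expect_equal(
    unname(pstnp_features(q, m, "ds")),
    oracle_pstnp_encode(oracle_ds_reduce(q),
                        oracle_pstnp_fit(sapply(pos, oracle_ds_reduce),
                                         sapply(neg, oracle_ds_reduce),
                                         alphabet = c("A", "C")))
  )
})

test_that("PSTNP propensities are bounded and antisymmetric in the classes", {
  set.seed(19)
  pos <- replicate(6, random_window())
  neg <- replicate(4, random_window())
  m <- fit_pstnp(pos, neg)
  m_swapped <- fit_pstnp(neg, pos)
  expect_true(all(abs(m$Zss) <= 1) && all(abs(m$Zds) <= 1))
  expect_equal(m_swapped$Zss, -m$Zss)
  expect_equal(m_swapped$Zds, -m$Zds)

  # all-zero model encodes any query to zero
  zero <- fit_pstnp(pos, pos)
  expect_equal(sum(abs(pstnp_features(random_window(), zero, "ss"))), 0)
  # degenerate model encodes poly-A to all ones
  ones <- fit_pstnp(strrep("A", 41), strrep("C", 41))
  expect_equal(unname(pstnp_features(strrep("A", 41), ones, "ss")), rep(1, 39))
})

test_that("PSTNP errors on empty classes and length mismatches", {
  expect_error(fit_pstnp(character(0), "AAA"), "non-empty")
  expect_error(fit_pstnp("AAAA", "AAA"), "one length")
  m <- fit_pstnp(strrep("A", 41), strrep("C", 41))
  expect_error(pstnp_features("ACGT", m, "ss"), "does not match")
})

test_that("property standardization gives mean 0, sd 1, and matches a z-score", {
  raw <- tibble::tibble(dinucleotide = sixmapred:::dinucleotides(),
                        p1 = as.numeric(1:16), p2 = rnorm(16))
  std <- standardize_properties(raw)
  for (p in c("p1", "p2")) {
    expect_equal(mean(std[[p]]), 0, tolerance = 1e-9)
    expect_equal(sd(std[[p]]), 1, tolerance = 1e-9)
  }
  expect_equal(std$p1, (1:16 - mean(1:16)) / sd(1:16))
  raw$p1 <- 5
  expect_error(standardize_properties(raw), "zero standard deviation")
})

test_that("bundled property table is standardized and complement-symmetric", {
  tab <- dinuc_properties()
  props <- setdiff(names(tab), "dinucleotide")
  expect_length(props, 6)
  for (p in props) {
    expect_equal(mean(tab[[p]]), 0, tolerance = 1e-9)
    expect_equal(sd(tab[[p]]), 1, tolerance = 1e-9)
  }
  raw <- dinuc_properties(standardize = FALSE)
  rc <- function(d) chartr("ACGT", "TGCA",
                           paste0(rev(strsplit(d, "")[[1]]), collapse = ""))
  for (p in props) {
    for (d in raw$dinucleotide) {
      expect_equal(raw[[p]][raw$dinucleotide == d],
                   raw[[p]][raw$dinucleotide == rc(d)])
    }
  }
})

test_that("physicochemical features match the double-loop oracle", {
  set.seed(23)
  toy <- "ACGTTGCAGA"  # 10 nt
  raw <- tibble::tibble(dinucleotide = sixmapred:::dinucleotides(),
                        a = rnorm(16), b = runif(16), c = rnorm(16, sd = 4))
  std <- standardize_properties(raw)
  got <- physicochemical_features(toy, std, lam = 5)
  expect_length(got, 15)
  expect_equal(unname(got), oracle_physchem(toy, std, lam = 5))

  # default table on a full window, all 30 values
  w <- random_window()
  expect_equal(unname(physicochemical_features(w)),
               oracle_physchem(w, dinuc_properties(), lam = 5))
})

test_that("physicochemical features respect product structure and lag switch", {
  zero_tab <- dinuc_properties()
  props <- setdiff(names(zero_tab), "dinucleotide")
  w <- random_window()

  # only one nonzero property -> other property slots are exactly 0
  one <- zero_tab
  for (p in props[-1]) one[[p]] <- one[[p]] * 0
  v <- suppressWarnings(physicochemical_features(w, one, lam = 5))
  mask <- rep(seq_along(props), times = 5) != 1
  expect_equal(sum(abs(v[mask])), 0)

  # permuting properties permutes the per-lag blocks correspondingly
  tab <- dinuc_properties()
  perm <- c("dinucleotide", rev(props))
  v1 <- physicochemical_features(w, tab, lam = 3)
  v2 <- physicochemical_features(w, tab[perm], lam = 3)
  reorder <- c(6:1, 12:7, 18:13)
  expect_equal(unname(v2), unname(v1)[reorder])

  # per-lag normalizer rescales each lag block by (L-3)/(L-2-m)
  v_fixed <- physicochemical_features(w, tab, lam = 2)
  v_perlag <- physicochemical_features(w, tab, lam = 2, normalize_per_lag = TRUE)
  L <- 41
  expect_equal(unname(v_perlag[1:6]), unname(v_fixed[1:6]) * (L - 3) / (L - 3))
  expect_equal(unname(v_perlag[7:12]), unname(v_fixed[7:12]) * (L - 3) / (L - 4))

  expect_error(physicochemical_features("ACGTA", lam = 5), "less than")
})

test_that("full encoding is the fixed-order concatenation of the blocks", {
  set.seed(29)
  pos <- replicate(4, random_window())
  neg <- replicate(4, random_window())
  m <- fit_pstnp(pos, neg)
  w <- random_window()
  v <- extract_all(w, m)
  expect_length(v, 172)
  expect_identical(names(v), feature_schema())
  expect_equal(v[1:64], eiip_features(w))
  expect_equal(v[65:103], pstnp_features(w, m, "ss"))
  expect_equal(v[104:142], pstnp_features(w, m, "ds"))
  expect_equal(v[143:172], physicochemical_features(w))
  # encoders are pure: identical input, bit-identical output
  expect_identical(v, extract_all(w, m))

  feats <- featurize(tibble::tibble(id = c("a", "b"), seq = c(w, pos[1]),
                                    label = c("unknown", "positive")), m)
  expect_equal(dim(feats), c(2, 174))
  expect_identical(names(feats)[-(1:2)], feature_schema())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(feats, f)
  expect_equal(as.data.frame(read_feature_matrix(f)), as.data.frame(feats))
})

test_that("positional entropy matches closed forms and is order-invariant", {
  expect_equal(positional_entropy(rep(strrep("A", 41), 5))$entropy, rep(0, 39))

  # 64 samples covering every trinucleotide once at position 1 -> 6 bits there
  tris <- sixmapred:::trinucleotides()
  samples64 <- paste0(tris, strrep("A", 38))
  prof <- positional_entropy(samples64)
  expect_equal(nrow(prof), 39)
  expect_equal(prof$entropy[1], 6)

  # two equally frequent trinucleotides -> 1 bit
  two <- c(strrep("A", 41), paste0("CCC", strrep("A", 38)))
  expect_equal(positional_entropy(two)$entropy[1], 1)

  set.seed(31)
  seqs <- replicate(20, random_window())
  p1 <- positional_entropy(seqs)
  p2 <- positional_entropy(rev(seqs))
  expect_equal(p1, p2)
  expect_true(all(p1$entropy >= 0 & p1$entropy <= 6))
  expect_equal(p1$entropy[5], oracle_entropy_at(seqs, 5))

  expect_error(positional_entropy(character(0)), "empty")
})
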