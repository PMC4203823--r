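test_that("pair_stdevp is the population SD of a two-element set", {
  expect_equal(pair_stdevp(1, 0), 0.5)
  expect_equal(pair_stdevp(0.9, 0.1), 0.4)
  expect_equal(pair_stdevp(3, 3), 0)
  set.seed(50)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pair_stdevp(a, b), pair_stdevp(b, a))
  expect_true(all(pair_stdevp(a, b) >= 0))
  expect_equal(which(pair_stdevp(a, a) == 0), 1:30)
  # agrees with the n-denominator SD formula applied to each pair
  expect_equal(pair_stdevp(a[1], b[1]),
               sqrt(mean((c(a[1], b[1]) - mean(c(a[1], b[1])))^2)))
})

test_that("unit-variance-no-centring scaling has unit mean square and degree-0 homogeneity", {
  expect_equal(scale_unit_variance_nocenter(c(2, 2, 2)), c(1, 1, 1))
  expect_equal(scale_unit_variance_nocenter(c(3, -4)),
               c(3 / sqrt(12.5), -4 / sqrt(12.5)))
  set.seed(51)
  for (i in 1:10) {
    v <- rnorm(7)
    s <- scale_unit_variance_nocenter(v)
    expect_equal(mean(s^2), 1, tolerance = 1e-12)
    expect_equal(scale_unit_variance_nocenter(17.3 * v), s, tolerance = 1e-12)
  }
  expect_error(scale_unit_variance_nocenter(rep(0, 4)), "zero")
})

test_that("community distributions sum the right members and conserve totals", {
  d <- tiny_fused()
  m <- filter_otus_by_max_abs_correlation(correlation_matrix(d), 0.7)
  part <- cluster_bgc_types(m, k = 2, seed = 2, n_init = 25)
  dist <- community_distribution(part, d$community)
  expect_true(all(dist$abundance >= 0 & dist$abundance <= 1))

  # conservation: per-sample sums over types equal the filtered subset sums
  per_sample <- tapply(dist$abundance, dist$sample, sum)
  subset_sums <- colSums(d$community$values[names(part$labels), , drop = FALSE])
  expect_equal(as.numeric(per_sample[names(subset_sums)]),
               as.numeric(subset_sums), tolerance = 1e-12)

  # all OTUs in one type equals the domain column sums
  all_in_one <- part
  all_in_one$labels[] <- 1L
  all_in_one$k <- 1L
  d1 <- community_distribution(all_in_one, d$community)
  expect_equal(as.numeric(d1$abundance[match(names(subset_sums), d1$sample)]),
               as.numeric(subset_sums), tolerance = 1e-12)

  bad <- part
  names(bad$labels)[1] <- "16S:ghost"
  expect_error(community_distribution(bad, d$community), "ghost")
})

test_that("taxonomy collapse aggregates at class with fallback and sums to 100", {
  v <- matrix(c(0.1, 0.1,  0.3, 0.3,  0.2, 0.2,  0.4, 0.4), 4, 2, byrow = TRUE,
              dimnames = list(paste0("16S:o", 1:4), c("s1", "s2")))
  tax <- list(`16S:o1` = c("Bacteria", "P1", "ClassA"),
              `16S:o2` = c("Bacteria", "P1", "ClassA"),
              `16S:o3` = c("Bacteria", "P2"),          # truncated at phylum
              `16S:o4` = character(0))                  # unassigned
  comm <- feature_table(v, "fused_community", "relative_abundance",
                        taxonomy = tax)
  part <- structure(list(labels = stats::setNames(c(1L, 1L, 2L, 2L),
                                                  rownames(v)),
                         k = 2L, pca = NULL), class = "bgc_partition")
  br <- collapse_taxonomy(part, comm)
  t1 <- br[br$type == 1, ]
  expect_equal(t1$taxon, "ClassA")
  expect_equal(t1$percent, 100)
  t2 <- br[br$type == 2, ]
  expect_setequal(t2$taxon, c("P2", "Unassigned"))
  expect_equal(sum(t2$percent), 100, tolerance = 1e-6)
  # abundance weighting: o3 carries 0.4 of weight, o4 carries 0.8
  expect_equal(t2$percent[t2$taxon == "P2"], 100 * 0.4 / 1.2, tolerance = 1e-6)
})

test_that("equal-abundance classes split evenly", {
  v <- matrix(0.25, 4, 3, dimnames = list(paste0("18S:o", 1:4),
                                          paste0("s", 1:3)))
  tax <- lapply(1:4, function(i) c("Eukaryota", "P", paste0("Class", i)))
  names(tax) <- rownames(v)
  comm <- feature_table(v, "fused_community", "relative_abundance",
                        taxonomy = tax)
  part <- structure(list(labels = stats::setNames(rep(1L, 4), rownames(v)),
                         k = 1L, pca = NULL), class = "bgc_partition")
  br <- collapse_taxonomy(part, comm)
  expect_equal(br$percent, rep(25, 4), tolerance = 1e-6)
})

test_that("explaining PC follows the larger absolute centroid score", {
  mk_part <- function(scores, labels) {
    structure(list(labels = labels, k = length(unique(labels)),
                   pca = list(scores = scores)), class = "bgc_partition")
  }
  sc <- rbind(a = c(5.0, 0.2), b = c(4.8, 0.1), c = c(0.1, -3.0), d = c(0.2, -2.8))
  colnames(sc) <- c("PC1", "PC2")
  lab <- stats::setNames(c(1L, 1L, 2L, 2L), rownames(sc))
  expect_equal(unname(select_explaining_pc(mk_part(sc, lab))), c(1L, 2L))

  tie <- rbind(a = c(2, 2), b = c(2, 2))
  colnames(tie) <- c("PC1", "PC2")
  lab1 <- stats::setNames(c(1L, 1L), rownames(tie))
  expect_warning(res <- select_explaining_pc(mk_part(tie, lab1)), "tied")
  expect_equal(unname(res), 1L)
})

test_that("cross-wise planted geometry maps two types to PC1 and two to PC2", {
  # Four blocks whose correlation signatures sit at +-u and +-v for two
  # orthogonal directions u, v: the score plot is a cross.
  set.seed(52)
  u <- c(rep(0.9, 3), rep(0, 3), rep(0, 2))
  v <- c(rep(0, 3), rep(0.9, 3), rep(0, 2))
  centers <- rbind(1.1 * u, -1.1 * u, v, -v)  # PC1 pair slightly stronger
  rho <- centers[rep(1:4, each = 8), ] +
    matrix(rnorm(32 * 8, 0, 0.02), 32, 8)
  rho <- pmin(pmax(rho, -1), 1)
  dimnames(rho) <- list(sprintf("16S:o%02d", 1:32), sprintf("nmr:c%d", 1:8))
  m <- structure(list(rho = rho,
                      undefined_mask = matrix(FALSE, 32, 8,
                                              dimnames = dimnames(rho)),
                      n_samples = 14L, chem_blocks = rep("nmr", 8)),
                 class = "bgc_corr")
  part <- cluster_bgc_types(m, k = 4, seed = 5, n_init = 30)
  expl <- select_explaining_pc(part)
  expect_setequal(as.integer(table(expl)), c(2L, 2L))
})

test_that("chemical-profile extraction flags planted variables, never negative ones", {
  set.seed(53)
  ds <- generate_bgc_dataset(bgc_synth_spec(seed = 12))
  fit <- bgc_typing(ds$community, ds$chemicals, seed = 12)
  prof <- chem_profile(fit)

  # sign rule: negative average correlation is never extracted
  expect_false(any(prof$extracted & prof$avg_rho <= 0))

  # planted variables of the matched type are extracted, unrelated nulls not
  lab <- labels(fit)
  map <- map_types_to_truth(lab, ds$truth$otu_types)
  chem_truth <- ds$truth$chem_types
  hit <- 0; n_own <- 0; null_extracted <- 0
  for (g in sort(unique(prof$type))) {
    sub <- prof[prof$type == g, ]
    own <- sub$chem_id[chem_truth[sub$chem_id] == map[g]]
    n_own <- n_own + length(own)
    hit <- hit + sum(sub$extracted[match(own, sub$chem_id)])
    null_extracted <- null_extracted +
      sum(sub$extracted[chem_truth[sub$chem_id] == 0])
  }
  expect_gte(hit / n_own, 0.8)
  expect_lte(null_extracted, 2)

  # structural invariant from the rule itself
  cut <- attr(prof, "cut")
  expect_true(all(prof$stdevp[prof$extracted] >= cut))
  expect_true(all(prof$avg_rho[prof$extracted] > 0))

  # rows come grouped by chemical platform
  blocks <- prof$block[prof$type == prof$type[1]]
  expect_identical(blocks, blocks[order(match(blocks, c("icp", "ftir", "nmr")))])
})

test_that("empty clusters abort chemical profiling", {
  d <- tiny_fused()
  m <- filter_otus_by_max_abs_correlation(correlation_matrix(d), 0.7)
  part <- cluster_bgc_types(m, k = 2, seed = 2, n_init = 25)
  broken <- part
  broken$labels[] <- 1L  # type 2 left empty
  expect_error(extract_chemical_profile(m, broken, pca = part$pca), "no member")
})
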