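# Shrinkage trees, activity-group assignment, prior density.

test_that("build_hierarchy constructs the married geographic tree", {
  meta <- data.frame(
    country_code = adolfp:::iso_codes(12),
    name = "x",
    subregion = rep(paste0("S", 1:4), each = 3),
    region = rep(c("R1", "R2"), each = 6),
    activity_group = 1L, stringsAsFactors = FALSE)
  tree <- build_hierarchy(meta, "married")
  expect_equal(tree$levels, c("world", "region", "subregion", "country"))
  expect_equal(sum(tree$nodes$level == "country"), 12)
  expect_equal(sum(tree$nodes$level == "region"), 2)
  expect_equal(sum(tree$nodes$level == "subregion"), 4)
  # each country has exactly one parent chain to the root
  for (code in meta$country_code) {
    p <- tree$country_parent[[code]]
    chain <- p
    while (!is.na(p)) {
      p <- tree$nodes$parent[tree$nodes$id == p]
      chain <- c(chain, p)
    }
    expect_equal(chain[length(chain) - 1], "world")
  }
})

test_that("unmarried tree nests subregions inside activity groups", {
  meta <- make_meta(c("AAA", "AAB", "AAC", "AAD"),
                    subregion = rep(c("S1", "S2"), each = 2),
                    region = "R1", activity_group = 1L)
  tree <- build_hierarchy(meta, "unmarried")
  expect_true(all(c("g:0", "g:1") %in% tree$nodes$id))
  # all subregions in group 1 -> group 0 present but childless
  expect_equal(sum(tree$nodes$parent == "g:0", na.rm = TRUE), 0)
  expect_gt(sum(tree$nodes$parent == "g:1", na.rm = TRUE), 0)

  # a subregion split across groups is an error
  meta_bad <- meta; meta_bad$activity_group <- c(0L, 1L, 1L, 1L)
  expect_error(build_hierarchy(meta_bad, "unmarried"), "spans")
})

test_that("duplicate and incomplete metadata are rejected", {
  meta <- make_meta(c("AAA", "AAA"))
  expect_error(build_hierarchy(meta, "married"), "more than once")
  meta2 <- make_meta("AAA"); meta2$subregion <- NA
  expect_error(build_hierarchy(meta2, "married"), "subregion")
})

test_that("assign_activity_group uses an inclusive 2% threshold", {
  expect_equal(assign_activity_group(1.5), 0L)
  expect_equal(assign_activity_group(2.0), 0L)   # "not more than 2%"
  expect_equal(assign_activity_group(2.01), 1L)
  expect_equal(assign_activity_group(10), 1L)
  expect_equal(assign_activity_group(NA, fallback = 1), 1L)
  expect_error(assign_activity_group(NA), "fallback|metadata")
  expect_error(assign_activity_group(120), "\\[0, 100\\]")
})

test_that("prior_logdensity sums shrinkage terms with known differences", {
  meta <- make_meta(c("AAA", "AAB"))
  tree <- build_hierarchy(meta, "married")
  nd <- adolfp:::internal_nodes(tree)
  pr <- tree$priors
  node_means <- matrix(rep(pr$root_mean, each = nrow(nd)), nrow(nd),
                       dimnames = list(nd$id, adolfp:::PARAM_NAMES))
  level_sds <- matrix(1, 3, 7,
                      dimnames = list(c("region", "subregion", "country"),
                                      adolfp:::PARAM_NAMES))
  theta <- matrix(rep(pr$root_mean, each = 2), 2,
                  dimnames = list(meta$country_code,
                                  adolfp:::PARAM_NAMES))
  base <- prior_logdensity(theta, node_means, level_sds, tree)

  # moving one country off its subregion mean by d changes the density
  # by the analytic normal amount (unit sds)
  theta2 <- theta; theta2["AAA", "la_any"] <- theta["AAA", "la_any"] + 0.7
  d <- prior_logdensity(theta2, node_means, level_sds, tree) - base
  expect_equal(d, dnorm(0.7, log = TRUE) - dnorm(0, log = TRUE),
               tolerance = 1e-12)

  # doubling a level sd with fixed residuals: analytic difference in
  # both the shrinkage terms and the half-normal hyperprior
  sds2 <- level_sds; sds2["country", "la_any"] <- 2
  d2 <- prior_logdensity(theta2, node_means, sds2, tree) -
    prior_logdensity(theta2, node_means, level_sds, tree)
  analytic <-
    sum(dnorm(c(0.7, 0), 0, 2, log = TRUE) -
          dnorm(c(0.7, 0), 0, 1, log = TRUE)) +
    (adolfp:::dhalfnorm_log(2, pr$hn_scale["country", "la_any"]) -
       adolfp:::dhalfnorm_log(1, pr$hn_scale["country", "la_any"]))
  expect_equal(d2, analytic, tolerance = 1e-12)
})

test_that("a one-country tree reduces to a chained normal prior", {
  meta <- make_meta("AAA")
  tree <- build_hierarchy(meta, "married")
  nd <- adolfp:::internal_nodes(tree)
  pr <- tree$priors
  node_means <- matrix(0, nrow(nd), 7,
                       dimnames = list(nd$id, adolfp:::PARAM_NAMES))
  level_sds <- matrix(1, 3, 7,
                      dimnames = list(c("region", "subregion", "country"),
                                      adolfp:::PARAM_NAMES))
  theta <- matrix(0.5, 1, 7, dimnames = list("AAA",
                                             adolfp:::PARAM_NAMES))
  ld <- prior_logdensity(theta, node_means, level_sds, tree)
  manual <- sum(dnorm(0, pr$root_mean, pr$root_sd, log = TRUE)) +
    sum(adolfp:::dhalfnorm_log(1, pr$hn_scale["region", ])) +
    sum(adolfp:::dhalfnorm_log(1, pr$hn_scale["subregion", ])) +
    sum(adolfp:::dhalfnorm_log(1, pr$hn_scale["country", ])) +
    2 * 7 * dnorm(0, 0, 1, log = TRUE) +  # region, subregion at parent
    7 * dnorm(0.5, 0, 1, log = TRUE)
  expect_equal(ld, manual, tolerance = 1e-10)
})

test_that("one country's data never alters another's conditional prior", {
  # structural independence: the prior factorises over countries given
  # node means and sds, so changing country A's value leaves country
  # B's conditional term unchanged
  meta <- make_meta(c("AAA", "AAB"))
  tree <- build_hierarchy(meta, "married")
  nd <- adolfp:::internal_nodes(tree)
  node_means <- matrix(0, nrow(nd), 7,
                       dimnames = list(nd$id, adolfp:::PARAM_NAMES))
  level_sds <- matrix(1, 3, 7,
                      dimnames = list(c("region", "subregion", "country"),
                                      adolfp:::PARAM_NAMES))
  thA <- matrix(c(0, 0.4), 2, 7, dimnames = list(c("AAA", "AAB"),
                                                 adolfp:::PARAM_NAMES))
  thB <- thA; thB["AAA", ] <- 3
  dA <- prior_logdensity(thA, node_means, level_sds, tree)
  dB <- prior_logdensity(thB, node_means, level_sds, tree)
  # difference involves only AAA terms
  expect_equal(dB - dA,
               sum(dnorm(3, 0, 1, log = TRUE)) * 7 -
                 sum(dnorm(thA["AAA", ], 0, 1, log = TRUE)),
               tolerance = 1e-10)
})
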