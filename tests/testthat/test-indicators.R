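# Indicator algebra on constructed draw arrays, including the worked
# identities from the published global estimates.

test_that("combine_marital reproduces the worked 1990 world estimate", {
  # married any-method use 15.2%, unmarried 3.8%, 18.5% married:
  # all-women use = 0.185*15.2 + 0.815*3.8 = 5.9%
  married <- const_prop(list(W = c(0.10, 0.052, 0.20, 0.648)),
                        marital_group = "married")
  unmarried <- const_prop(list(W = c(0.030, 0.008, 0.01, 0.952)),
                          marital_group = "unmarried")
  demog <- make_demog("W", w = 0.185)
  allw <- combine_marital(married, unmarried, demog)
  use_all <- allw$comp[1, 1, 1, 1] + allw$comp[1, 1, 1, 2]
  expect_equal(round(100 * use_all, 1), 5.9)
  expect_equal(use_all, 0.185 * 0.152 + 0.815 * 0.038, tolerance = 1e-12)

  # w = 1: all-women equals married
  demog1 <- make_demog("W", w = 1)
  all1 <- combine_marital(married, unmarried, demog1)
  expect_equal(all1$comp, married$comp)

  # convexity at every draw
  set.seed(3)
  m <- const_prop(list(W = c(0.2, 0.1, 0.15, 0.55)), n_draws = 150)
  u <- const_prop(list(W = c(0.05, 0.02, 0.03, 0.90)), n_draws = 150,
                  marital_group = "unmarried")
  aw <- combine_marital(m, u, make_demog("W", w = 0.3))
  for (k in 1:4) {
    lo <- pmin(m$comp[, 1, 1, k], u$comp[, 1, 1, k])
    hi <- pmax(m$comp[, 1, 1, k], u$comp[, 1, 1, k])
    expect_true(all(aw$comp[, 1, 1, k] >= lo - 1e-12 &
                      aw$comp[, 1, 1, k] <= hi + 1e-12))
  }

  bad <- const_prop(list(W = c(0.2, 0.1, 0.15, 0.55)), n_draws = 120)
  expect_error(combine_marital(m, bad, make_demog("W")), "same grid")
})

test_that("counts transform proportions by group population", {
  prop <- const_prop(list(W = c(0.06, 0.04, 0.05, 0.85)),
                     marital_group = "all")
  demog <- make_demog("W", pop = 3e8, w = 0.2)
  cnt <- counts_from_proportions(prop, demog)
  expect_equal(cnt$count[1, 1, 1, 1] + cnt$count[1, 1, 1, 2], 3e7)
  # zero population -> zero counts
  cnt0 <- counts_from_proportions(prop, make_demog("W", pop = 0))
  expect_true(all(cnt0$count == 0))
  # marital splits use the complementary populations
  m <- const_prop(list(W = c(0.2, 0.1, 0.1, 0.6)))
  cm <- counts_from_proportions(m, demog)
  expect_equal(cm$pop[1, 1], 0.2 * 3e8)
  u <- const_prop(list(W = c(0.2, 0.1, 0.1, 0.6)),
                  marital_group = "unmarried")
  cu <- counts_from_proportions(u, demog)
  expect_equal(cu$pop[1, 1], 0.8 * 3e8)
})

test_that("married and unmarried user counts add to the all-women count", {
  # world 2019: 11.0 M married + 18.8 M unmarried = 29.8 M users
  pop <- 3e8; w <- 0.123
  m_any <- 11.0e6 / (w * pop); u_any <- 18.8e6 / ((1 - w) * pop)
  married <- const_prop(list(W = c(m_any * 0.85, m_any * 0.15, 0.1,
                                   0.9 - m_any)))
  unmarried <- const_prop(list(W = c(u_any * 0.9, u_any * 0.1, 0.02,
                                     0.98 - u_any)),
                          marital_group = "unmarried")
  demog <- make_demog("W", pop = pop, w = w)
  cm <- counts_from_proportions(married, demog)
  cu <- counts_from_proportions(unmarried, demog)
  call <- counts_from_proportions(combine_marital(married, unmarried,
                                                  demog), demog)
  users <- function(cnt) cnt$count[1, 1, 1, 1] + cnt$count[1, 1, 1, 2]
  expect_equal(users(cm) + users(cu), users(call), tolerance = 1e-6)
  expect_equal(round(users(call) / 1e6, 1), 29.8)
})

test_that("aggregation sums counts draw-wise and checks membership", {
  comp <- list(AAA = c(0.2, 0.1, 0.1, 0.6), AAB = c(0.2, 0.1, 0.1, 0.6),
               AAC = c(0.4, 0.05, 0.2, 0.35))
  prop <- const_prop(comp, marital_group = "all")
  demog <- make_demog(names(comp), pop = 1e6)
  cnt <- counts_from_proportions(prop, demog)

  # two identical countries -> aggregate doubles every draw
  sp2 <- aggregate_spec("region", list(R = c("AAA", "AAB")))
  agg2 <- aggregate_counts(cnt, sp2)
  expect_equal(agg2$count[, 1, 1, ], 2 * cnt$count[, 1, 1, ])

  # world equals the sum of disjoint regions exactly, per draw
  spw <- aggregate_spec("world", list(World = names(comp)))
  spr <- aggregate_spec("region", list(R1 = c("AAA", "AAB"), R2 = "AAC"))
  w <- aggregate_counts(cnt, spw)
  r <- aggregate_counts(cnt, spr)
  expect_identical(w$count[, 1, 1, ],
                   r$count[, 1, 1, ] + r$count[, 2, 1, ])

  # single-member aggregate equals the member
  expect_equal(r$count[, 2, , ], cnt$count[, 3, , ])

  expect_error(aggregate_spec("region", list(R1 = c("AAA", "AAB"),
                                             R2 = c("AAB", "AAC"))),
               "overlap")
  expect_error(aggregate_counts(cnt, aggregate_spec("region",
                                                    list(R = "ZZZ"))),
               "not present")

  # aggregate proportions are count-weighted
  pr <- as_proportions(r)
  expect_equal(pr$comp[1, "R1", 1, 1],
               (cnt$count[1, 1, 1, 1] + cnt$count[1, 2, 1, 1]) / 2e6)
})

test_that("need_satisfied_modern reproduces the married world figure", {
  # married world 2019: modern 26.2%, any 30.9%, unmet 20.7%
  # -> need 51.6%, SDG 3.7.1 = 26.2 / 51.6 = 50.8%
  m <- const_prop(list(W = c(0.262, 0.047, 0.207, 0.484)))
  nsm <- need_satisfied_modern(m)
  expect_equal(round(100 * nsm[1, 1, 1], 1), 50.8)
  expect_equal(nsm[1, 1, 1], 0.262 / 0.516, tolerance = 1e-12)

  # edge cases
  z <- const_prop(list(W = c(0, 0.1, 0.1, 0.8)))
  expect_equal(need_satisfied_modern(z)[1, 1, 1], 0)
  one <- const_prop(list(W = c(0.3, 0, 0, 0.7)))
  expect_equal(need_satisfied_modern(one)[1, 1, 1], 1)
  none <- const_prop(list(W = c(0, 0, 0, 1)))
  expect_true(is.na(need_satisfied_modern(none)[1, 1, 1]))
})

test_that("summarize_draws adjusts method medians and orders quantiles", {
  set.seed(5)
  n <- 2000
  arr <- array(NA_real_, c(n, 1, 1, 4),
               dimnames = list(NULL, "W", 2019,
                               c("modern", "traditional", "unmet",
                                 "no_need")))
  # asymmetric draws so the median identity genuinely needs adjustment
  p_any <- plogis(rnorm(n, qlogis(0.102), 0.2))
  r <- plogis(rnorm(n, qlogis(0.892), 0.3))
  u <- plogis(rnorm(n, qlogis(0.06), 0.2))
  arr[, 1, 1, 1] <- p_any * r
  arr[, 1, 1, 2] <- p_any * (1 - r)
  arr[, 1, 1, 3] <- (1 - p_any) * u
  arr[, 1, 1, 4] <- (1 - p_any) * (1 - u)
  x <- adolfp:::fp_prop(arr, 2019, "W", "all")
  rec <- summarize_draws(x)
  med <- setNames(rec$median, rec$indicator)
  # exact identity after adjustment
  expect_equal(med[["use_modern"]] + med[["use_traditional"]],
               med[["use_any"]], tolerance = 1e-12)
  # unadjusted medians do not satisfy it exactly (adjustment is real)
  expect_false(isTRUE(all.equal(
    median(arr[, 1, 1, 1]) + median(arr[, 1, 1, 2]),
    median(arr[, 1, 1, 1] + arr[, 1, 1, 2]), tolerance = 1e-12)))
  # intervals never adjusted: straight empirical percentiles
  expect_equal(rec$ui_low[rec$indicator == "use_any"],
               unname(quantile(p_any, 0.025)), tolerance = 1e-9)
  expect_true(all(rec$ui_low <= rec$median & rec$median <= rec$ui_high))

  # symmetric draws: median tracks the mean
  arr2 <- arr
  sym <- 0.3 + rnorm(n, 0, 0.01)
  arr2[, 1, 1, 1] <- sym; arr2[, 1, 1, 2] <- 0.1
  arr2[, 1, 1, 3] <- 0.1; arr2[, 1, 1, 4] <- 0.5 - (sym - 0.3)
  x2 <- adolfp:::fp_prop(arr2, 2019, "W", "all")
  rec2 <- summarize_draws(x2)
  expect_equal(rec2$median[rec2$indicator == "use_modern"],
               mean(sym), tolerance = 0.002)

  # identity already satisfied -> adjustment is a no-op
  x3 <- const_prop(list(W = c(0.2, 0.1, 0.1, 0.6)))
  rec3 <- summarize_draws(x3)
  expect_equal(rec3$median[rec3$indicator == "use_modern"], 0.2)

  expect_error(summarize_draws(const_prop(list(W = c(0.2, 0.1, 0.1, 0.6)),
                                          n_draws = 50)),
               "at least")
})

test_that("the published modern-share figure follows from its medians", {
  # 9.1% modern of 10.2% any-method use -> 89.2% of users on a modern
  # method
  expect_equal(round(100 * 9.1 / 10.2, 1), 89.2)
})

test_that("suppression flags low-count countries but keeps aggregates", {
  meta <- make_meta(c("AAA", "AAB", "AAC"))
  demog <- make_demog(c("AAA", "AAB", "AAC"))
  obs <- rbind(make_obs("AAA"), make_obs("AAB"),
               make_obs("AAB", year = 2012.5))
  counts <- validate_dataset(obs, demog, meta)$obs_counts
  comp <- list(AAA = c(0.2, 0.1, 0.1, 0.6), AAB = c(0.2, 0.1, 0.1, 0.6),
               AAC = c(0.4, 0.05, 0.2, 0.35))
  prop <- const_prop(comp)
  rec <- summarize_draws(prop)
  sp <- aggregate_spec("region", list(R1 = names(comp)))
  out <- suppression_filter(rec, counts, sp)
  # 1 observation -> suppressed; 2 observations -> reported
  expect_true(all(out$suppressed[out$location == "AAA"]))
  expect_false(any(out$suppressed[out$location == "AAB"]))
  expect_true(all(out$suppressed[out$location == "AAC"]))

  # suppressed countries still contribute to the aggregate draws
  cnt <- counts_from_proportions(
    const_prop(comp, marital_group = "all"), demog)
  agg <- aggregate_counts(cnt, sp)
  expect_equal(agg$count[1, 1, 1, 1],
               sum(vapply(comp, `[`, numeric(1), 1)) * 1e5 / 1)

  # ratio suppression by women-in-need floor
  out2 <- suppression_filter(rec, counts, sp,
                             need_medians = c(AAB = 5e4))
  expect_true(all(out2$suppressed[out2$location == "AAB" &
                                    out2$indicator ==
                                      "need_satisfied_modern"]))
  expect_false(any(out2$suppressed[out2$location == "AAB" &
                                     out2$indicator == "use_any"]))

  # well-observed everywhere -> nothing suppressed
  obs_ok <- rbind(make_obs("AAA"), make_obs("AAA", year = 2012.5),
                  make_obs("AAB"), make_obs("AAB", year = 2012.5),
                  make_obs("AAC"), make_obs("AAC", year = 2012.5))
  counts_ok <- validate_dataset(obs_ok, demog, meta)$obs_counts
  expect_false(any(suppression_filter(rec, counts_ok, sp)$suppressed))
})

test_that("marital combination commutes with aggregation at the draw level", {
  codes <- c("AAA", "AAB", "AAC")
  set.seed(11)
  mk <- function(group) {
    comp <- lapply(codes, function(i) {
      x <- runif(4); x / sum(x)
    })
    names(comp) <- codes
    const_prop(comp, n_draws = 120, marital_group = group)
  }
  m <- mk("married"); u <- mk("unmarried")
  demog <- do.call(rbind, lapply(seq_along(codes), function(i) {
    data.frame(country_code = codes[i], year = 1970:2030,
               pop_15_19 = c(5e5, 8e5, 12e5)[i],
               prop_married = c(0.1, 0.25, 0.4)[i], filled = FALSE)
  }))
  sp <- aggregate_spec("world", list(World = codes))
  # combine then aggregate
  path1 <- aggregate_counts(
    counts_from_proportions(combine_marital(m, u, demog), demog), sp)
  # aggregate each group then combine the counts
  cm <- aggregate_counts(counts_from_proportions(m, demog), sp)
  cu <- aggregate_counts(counts_from_proportions(u, demog), sp)
  expect_equal(path1$count[, 1, , ], cm$count[, 1, , ] + cu$count[, 1, , ],
               tolerance = 1e-9)
})

test_that("adolescent_share is the ratio of category counts", {
  ado <- data.frame(location = "World", marital_group = "all",
                    indicator = c("use_any", "unmet"), scale = "count",
                    year = 2019, median = c(10, 40), ui_low = c(8, 30),
                    ui_high = c(12, 50), suppressed = FALSE)
  allage <- data.frame(location = "World", marital_group = "all",
                       indicator = c("use_any", "unmet"),
                       count = c(100, 40))
  sh <- adolescent_share(ado, allage)
  expect_equal(sh$share_pct, c(10, 100))
  expect_false(any(sh$suppressed))

  allage0 <- allage; allage0$count[1] <- 0
  sh0 <- adolescent_share(ado, allage0)
  expect_true(sh0$suppressed[1])
  expect_error(adolescent_share(ado, NULL), "not supplied")
})
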