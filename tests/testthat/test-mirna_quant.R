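# Spike-in equalization, censoring, global-mean normalization, detected
# sets, first-quartile selection and genetic-weight scoring.

test_that("spike-in equalization anchors panel B to the panel-A spike", {
  x <- tiny_crt_table(matrix(c(20, 21, 24, 23), nrow = 2, byrow = TRUE,
                             dimnames = list(c("mA", "mB"), NULL)),
                      panel_b = "mB", spike_a = c(15, 15), spike_b = c(16, 16))
  eq <- spike_in_equalize(x)
  expect_equal(unname(eq$crt["mB", ]), c(23, 22))   # shifted by 15 - 16
  expect_equal(unname(eq$crt["mA", ]), c(20, 21))   # panel A untouched
  expect_equal(unname(eq$spike_crt[, "B"]), c(15, 15))

  # equal spikes leave the table unchanged
  x2 <- tiny_crt_table(matrix(c(20, 21, 24, 23), nrow = 2, byrow = TRUE,
                              dimnames = list(c("mA", "mB"), NULL)),
                       panel_b = "mB", spike_a = c(15, 15), spike_b = c(15, 15))
  expect_equal(spike_in_equalize(x2)$crt, x2$crt)
})

test_that("a consistent shift of panel B and its spike is removed exactly", {
  base <- matrix(c(20, 21, 24, 23, 26, 25), nrow = 3, byrow = TRUE,
                 dimnames = list(c("mA", "mB1", "mB2"), NULL))
  x <- tiny_crt_table(base, panel_b = c("mB1", "mB2"),
                      spike_a = c(15, 15), spike_b = c(16, 16))
  shifted <- base
  shifted[c("mB1", "mB2"), ] <- shifted[c("mB1", "mB2"), ] + 2.5
  y <- tiny_crt_table(shifted, panel_b = c("mB1", "mB2"),
                      spike_a = c(15, 15), spike_b = c(18.5, 18.5))
  expect_equal(spike_in_equalize(y)$crt, spike_in_equalize(x)$crt)
})

test_that("equalization demands a spike on both panels when B is populated", {
  x <- tiny_crt_table(matrix(c(20, 21, 24, 23), nrow = 2, byrow = TRUE,
                             dimnames = list(c("mA", "mB"), NULL)),
                      panel_b = "mB")
  x$spike_crt[1, "A"] <- NA
  expect_error(spike_in_equalize(x), "spike-in")
})

test_that("censoring is strictly greater than the limit", {
  x <- tiny_crt_table(matrix(c(28.00, 28.01, 20, 35), nrow = 2, byrow = TRUE,
                             dimnames = list(c("m1", "m2"), NULL)))
  cen <- censor_unamplified(x)
  expect_equal(unname(cen$crt["m1", ]), c(28, NA))
  expect_equal(unname(cen$crt["m2", ]), c(20, NA))

  # an all-censored miRNA stays in the table and is flagged never-amplified
  y <- tiny_crt_table(matrix(c(20, 21, 30, 31), nrow = 2, byrow = TRUE,
                             dimnames = list(c("ok", "never"), NULL)))
  expr <- global_mean_normalize(censor_unamplified(y))
  expect_true("never" %in% rownames(expr$rel_expr))
  expect_equal(expr$never_amplified, "never")
})

test_that("global-mean normalization gives zero-mean dCrt and 2^-dCrt", {
  x <- tiny_crt_table(matrix(c(20, 20, 22, 22, 24, 24), nrow = 3, byrow = TRUE,
                             dimnames = list(c("m1", "m2", "m3"), NULL)))
  expr <- global_mean_normalize(censor_unamplified(x))
  expect_equal(unname(expr$delta_crt[, "S_R"]), c(-2, 0, 2))
  expect_equal(unname(expr$rel_expr[, "S_R"]), c(4, 1, 0.25))
  expect_equal(expr$rel_expr, 2^-expr$delta_crt)
  expect_lt(max(abs(colMeans(expr$delta_crt, na.rm = TRUE))), 1e-9)

  # single amplified miRNA: dCrt 0, rel_expr 1
  y <- tiny_crt_table(matrix(c(25, 24), nrow = 1,
                             dimnames = list("only", NULL)))
  ey <- global_mean_normalize(censor_unamplified(y))
  expect_equal(unname(ey$delta_crt["only", ]), c(0, 0))
  expect_equal(unname(ey$rel_expr["only", ]), c(1, 1))

  # sample with nothing amplified is a domain error
  z <- tiny_crt_table(matrix(c(30, 20), nrow = 1, dimnames = list("m", NULL)))
  expect_error(global_mean_normalize(censor_unamplified(z)), "zero amplified")
})

test_that("a per-sample global Crt shift leaves dCrt unchanged", {
  set.seed(21)
  base <- matrix(runif(12, 18, 27), nrow = 6,
                 dimnames = list(paste0("m", 1:6), NULL))
  x <- tiny_crt_table(base)
  shifted <- tiny_crt_table(sweep(base, 2, c(1, -0.7), "+"))
  e1 <- global_mean_normalize(censor_unamplified(x))
  e2 <- global_mean_normalize(censor_unamplified(shifted))
  expect_equal(e1$delta_crt, e2$delta_crt, tolerance = 1e-12)
  expect_equal(e1$rel_expr, e2$rel_expr, tolerance = 1e-12)
})

test_that("detection needs amplification in every sample of the condition", {
  samples <- four_donor_samples()
  crt <- matrix(24, 3, 8, dimnames = list(c("all", "partial", "lost"), samples$sample))
  crt["partial", "D3_R"] <- NA
  crt["lost", samples$sample[samples$condition == "primed"]] <- NA
  spike <- matrix(15, 8, 2, dimnames = list(samples$sample, c("A", "B")))
  x <- crt_table(crt, samples, stats::setNames(rep("A", 3), rownames(crt)), spike)
  det <- detected_sets(global_mean_normalize(censor_unamplified(x)))
  expect_false("partial" %in% det$resting)
  expect_true("partial" %in% det$primed)
  expect_equal(det$lost, "lost")
  expect_setequal(det$resting, c("all", "lost"))
  expect_setequal(det$primed, c("all", "partial"))
})

test_that("first-quartile selection keeps the top ceiling(n/4) deterministically", {
  set.seed(31)
  for (n in c(1:12, 56 * 4 - 2, 242, 555, sample(13:1000, 20))) {
    expr <- single_sample_expr(rlnorm(n))
    sel <- first_quartile_select(expr, "resting")
    expect_length(sel, ceiling(n / 4))
    m <- stats::setNames(expr$rel_expr[, 1], rownames(expr$rel_expr))
    expect_true(min(m[sel]) >= max(m[setdiff(names(m), sel)], -Inf))
  }
  # ties at the cutoff break lexicographically
  expr <- single_sample_expr(c(8, 1, 1, 1, 1, 1, 1, 1))
  sel <- first_quartile_select(expr, "resting")
  expect_equal(as.character(sel), c("m0001", "m0002"))
})

test_that("genetic weight normalizes to 100% and sums over partitions", {
  cfg <- synthetic_config(n_mirnas = 40, mirna_detect_both = 20, mirna_lost = 4,
                          mirna_gained = 4, category_sizes = c(synthetic_protective = 5),
                          seed = 8)
  expr <- global_mean_normalize(censor_unamplified(spike_in_equalize(
    generate_crt_table(cfg)$table)))
  det <- detected_sets(expr)$resting
  expect_equal(genetic_weight(expr, det, "resting")$weight, 100, tolerance = 1e-9)
  expect_equal(suppressWarnings(genetic_weight(expr, character(), "resting"))$weight, 0)
  # random partition sums to 100
  set.seed(41)
  grp <- sample(1:3, length(det), replace = TRUE)
  tot <- sum(vapply(1:3, function(g)
    genetic_weight(expr, det[grp == g], "resting")$weight, numeric(1)))
  expect_equal(tot, 100, tolerance = 1e-9)
  # undetected member warns and contributes zero
  expect_warning(gw <- genetic_weight(expr, c(det[1], "mir_9999"), "resting"),
                 "contributing 0")
  expect_equal(gw$member_weights$weight[gw$member_weights$mirna == "mir_9999"], 0)
})

test_that("weights match a brute-force recomputation from raw Crt", {
  set.seed(51)
  crt <- matrix(runif(16, 18, 27), nrow = 8,
                dimnames = list(paste0("m", 1:8), NULL))
  x <- tiny_crt_table(crt, panel_b = c("m7", "m8"))
  expr <- global_mean_normalize(censor_unamplified(spike_in_equalize(x)))
  subset <- c("m2", "m5", "m7")
  got <- genetic_weight(expr, subset, "resting")

  # direct formula substitution, independent of the pipeline code
  raw <- crt
  raw[c("m7", "m8"), ] <- raw[c("m7", "m8"), ] + (15 - 16)
  s <- 1  # resting sample
  rel <- 2^-(raw[, s] - mean(raw[, s]))
  expect_equal(got$weight, 100 * sum(rel[subset]) / sum(rel))
  expect_equal(got$member_weights$weight,
               unname(100 * rel[subset] / sum(rel)))
})

test_that("per-sample weighting variant averages within-sample shares", {
  samples <- four_donor_samples()[1:2, ]
  crt <- matrix(c(20, 22, 22, 20), nrow = 2,
                dimnames = list(c("m1", "m2"), samples$sample))
  spike <- matrix(15, 2, 2, dimnames = list(samples$sample, c("A", "B")))
  x <- crt_table(crt, samples, c(m1 = "A", m2 = "A"), spike)
  expr <- global_mean_normalize(censor_unamplified(x))
  # shares of m1: 80% in sample 1, 20% in sample 2
  gw <- genetic_weight(expr, "m1", "resting", method = "per_sample")
  expect_equal(gw$weight, 50)
  # condition-mean variant weights the mean expressions instead
  gm <- genetic_weight(expr, "m1", "resting")
  expect_equal(gm$weight, 50)  # symmetric case agrees
})

test_that("category balance reports deltas and their change across conditions", {
  mk <- function(w, cond, nm) structure(
    list(name = nm, condition = cond, weight = w,
         member_weights = tibble::tibble(), selection = character(),
         method = "condition_mean"),
    class = "genetic_weight_report")
  bal <- category_balance(mk(26.22, "resting", "M2"), mk(4.49, "resting", "M1"),
                          mk(28.76, "primed", "M2"), mk(3.61, "primed", "M1"))
  expect_equal(bal$delta, c(21.73, 25.15))
  expect_equal(attr(bal, "delta_change"), 3.42)
  expect_equal(category_balance(mk(5, "resting", "a"), mk(5, "resting", "b"))$delta, 0)
})

test_that("pipeline weights are invariant to spike-consistent panel shifts", {
  cfg <- synthetic_config(n_mirnas = 30, mirna_detect_both = 16, mirna_lost = 2,
                          mirna_gained = 2, category_sizes = c(synthetic_protective = 4),
                          seed = 13)
  x <- generate_crt_table(cfg)$table
  y <- x
  on_b <- names(y$panel_of)[y$panel_of == "B"]
  y$crt[on_b, ] <- y$crt[on_b, ] + 3
  y$spike_crt[, "B"] <- y$spike_crt[, "B"] + 3
  pipe <- function(t) global_mean_normalize(censor_unamplified(spike_in_equalize(t)))
  e1 <- pipe(x); e2 <- pipe(y)
  expect_equal(e1$rel_expr, e2$rel_expr, tolerance = 1e-12)
  det <- detected_sets(e1)$resting
  expect_equal(genetic_weight(e2, det[1:5], "resting")$weight,
               genetic_weight(e1, det[1:5], "resting")$weight, tolerance = 1e-12)
})
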