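# LRT machinery and the two selection screens (decision rules are tested
# on constructed fit objects; heavy Monte-Carlo calibration lives in the
# acceptance suite).

test_that("chi-square LRT reproduces textbook values", {
  expect_equal(lrt(0, 3.841 / 2, df = 1), 0.05, tolerance = 1e-3)
  expect_equal(lrt(-100, -100, df = 1), 1)
  expect_error(lrt(0, 1, df = 0), "df")
  # negative statistic within tolerance clamps to p = 1
  expect_equal(lrt(-99.99995, -100, df = 1), 1)
})

# minimal fit-shaped objects for the classifiers
mk_branch_fit <- function(l0, l1, l2, wf, wb, conv = TRUE, ne = 7) {
  tree <- ape::unroot(ape::rtree(5))
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  list(H0 = list(lnL = l0, converged = conv),
       H1 = list(lnL = l1, converged = conv,
                 omega = c(foreground = wf, background = wb),
                 tree = tree),
       H2 = list(lnL = l2, converged = conv))
}

test_that("fast-evolving calls follow the three-part decision rule", {
  fits <- list(
    sig_up = mk_branch_fit(-1000, -970, -969, wf = 1.2, wb = 0.2),
    sig_down = mk_branch_fit(-1000, -970, -969, wf = 0.1, wb = 0.6),
    ns = mk_branch_fit(-1000, -999.9, -999.8, wf = 0.5, wb = 0.2),
    h2_wins = mk_branch_fit(-1000, -970, -900, wf = 1.2, wb = 0.2))
  out <- classify_fast_evolving(fits, alpha = 0.01)
  res <- setNames(out$fast_evolving, out$family)
  expect_true(res[["sig_up"]])
  expect_false(res[["sig_down"]])   # direction rule
  expect_false(res[["ns"]])         # H1 not significant
  expect_false(res[["h2_wins"]])    # H2 significantly better than H1
})

test_that("unconverged families are excluded with a record", {
  fits <- list(ok = mk_branch_fit(-100, -80, -79, 1, 0.2),
               bad = mk_branch_fit(-100, -80, -79, 1, 0.2, conv = FALSE))
  out <- classify_fast_evolving(fits)
  expect_equal(attr(out, "excluded"), "bad")
  expect_equal(out$family, "ok")
})

test_that("positively-selected calls need significance and omega2 > 1", {
  mk_bs <- function(l0, l1, w2, conv = TRUE)
    list(null = list(lnL = l0, converged = conv),
         alt = list(lnL = l1, converged = conv, w2 = w2))
  fits <- list(sel = mk_bs(-500, -480, w2 = 4),
               no_sig = mk_bs(-500, -499.9, w2 = 4),
               w2_low = mk_bs(-500, -480, w2 = 1))
  out <- classify_positively_selected(fits, alpha = 0.01)
  res <- setNames(out$positively_selected, out$family)
  expect_true(res[["sel"]])
  expect_false(res[["no_sig"]])
  expect_false(res[["w2_low"]])
})

test_that("calls are invariant to family input order and BH is monotone", {
  set.seed(3)
  fits <- lapply(1:8, function(i) {
    l1 <- -1000 + rexp(1, 1 / 5)
    mk_branch_fit(-1000, l1, l1 + rexp(1, 2), wf = 1, wb = 0.2)
  })
  names(fits) <- paste0("f", 1:8)
  a <- classify_fast_evolving(fits)
  b <- classify_fast_evolving(rev(fits))
  b <- b[match(a$family, b$family), ]
  expect_equal(a$fast_evolving, b$fast_evolving)
  expect_equal(a$q_H1_vs_H0, b$q_H1_vs_H0)
  ord <- order(a$p_H1_vs_H0)
  expect_true(all(diff(a$q_H1_vs_H0[ord]) >= -1e-12))
})

test_that("screens combine into joint calls", {
  fast <- data.frame(family = c("a", "b", "c"),
                     fast_evolving = c(TRUE, TRUE, FALSE))
  ps <- data.frame(family = c("a", "b", "c"),
                   positively_selected = c(TRUE, FALSE, TRUE))
  out <- selection_calls(fast, ps)
  expect_equal(setNames(out$call, out$family),
               c(a = "both", b = "fast_evolving",
                 c = "positively_selected"))
})

test_that("branch-model ladder respects nesting and recovers omega", {
  tr <- read_tagged_tree("((A:0.15,B:0.15)#1:0.1,(C:0.15,D:0.15):0.1);")
  set.seed(77)
  sim <- sim_codon_alignment(tr, kappa = 2.5, omega = 0.3, n_codons = 500)
  fits <- fit_branch_models(sim$states, tr, fit_H2 = TRUE)
  expect_gte(fits$H1$lnL, fits$H0$lnL - 1e-3)
  expect_gte(fits$H2$lnL, fits$H1$lnL - 1e-3)
  # M0 omega-hat close to truth and to the NG86 counting estimate
  ng <- ng86_dnds(sim$sequences[["A"]], sim$sequences[["C"]])
  expect_lt(abs(fits$H0$omega[["omega"]] - 0.3), 0.12)
  expect_lt(abs(fits$H0$omega[["omega"]] - ng$omega),
            0.15 * max(ng$omega, fits$H0$omega[["omega"]]) + 0.05)
})

test_that("branch-site alternative detects a strong planted signal", {
  # six taxa: background branches pin down the purifying classes, which
  # the branch-site test needs for power
  tr <- read_tagged_tree(paste0(
    "((((A:0.05,B:0.05):0.04,C:0.09)#1:0.06,D:0.15):0.06,",
    "(E:0.12,F:0.12):0.06);"))
  ut <- panforge:::unroot_tagged(tr)
  fg <- foreground_edges(ut)
  expect_length(fg, 1)
  set.seed(98)
  # 70% of sites purifying everywhere, 30% at omega = 8 on the
  # foreground branch only
  W <- matrix(0.1, 2, nrow(ut$edge))
  W[2, fg] <- 8
  sim <- sim_codon_alignment(ut, kappa = 2.5, omega = W,
                             n_codons = 1000, class_props = c(0.7, 0.3))
  fits <- fit_branchsite_models(sim$states, tr, w2_starts = c(1.5, 8))
  expect_gte(fits$alt$lnL, fits$null$lnL - 1e-3)
  p <- lrt(fits$null$lnL, fits$alt$lnL, df = 1)
  expect_lt(p, 0.01)
  expect_gt(fits$alt$w2, 1)
})
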