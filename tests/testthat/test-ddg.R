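mk_est <- function(dG, method = "BAR", se = NA_real_) {
  neqsel:::fe_estimate(dG, method, se = se)
}

mk_ddg_row <- function(i, j, target, ddG, se = 0.1, method = "BAR",
                       conformer = "default") {
  data.frame(compound_i = i, compound_j = j, target = target,
             conformer = conformer, method = method, ddG = ddG, se = se,
             stringsAsFactors = FALSE)
}

test_that("the thermodynamic cycle difference combines legs and errors", {
  out <- leg_difference(mk_est(12, se = 0.3), mk_est(2, se = 0.4),
                        pair = "1->2", target = "CDK2")
  expect_equal(out$ddG, 10)
  expect_equal(out$se, 0.5) # 3-4-5 quadrature
  expect_identical(out$compound_i, "2")
  expect_identical(out$compound_j, "1")

  same <- leg_difference(mk_est(4, se = 0), mk_est(4, se = 0), "1->3", "CDK1")
  expect_equal(same$ddG, 0)

  expect_error(leg_difference(mk_est(1, "BAR"), mk_est(1, "CGI"), "1->2", "CDK2"),
               "different methods")
})

test_that("conformer selection takes the lowest ddG with lexicographic ties", {
  cand <- rbind(mk_ddg_row("2", "1", "CDK2", -4.1, conformer = "sin"),
                mk_ddg_row("2", "1", "CDK2", -2.0, conformer = "anti"))
  sel <- select_conformer(cand)
  expect_identical(sel$conformer, "sin")
  expect_true(sel$selected)
  expect_equal(sel$se, 0.1) # chosen conformer's own SE carried unchanged

  single <- select_conformer(mk_ddg_row("2", "1", "CDK2", 1))
  expect_true(single$selected)
  expect_equal(single$ddG, 1)

  tie <- rbind(mk_ddg_row("2", "1", "CDK2", -3, conformer = "sin"),
               mk_ddg_row("2", "1", "CDK2", -3, conformer = "anti"))
  expect_identical(select_conformer(tie)$conformer, "anti")

  # idempotent and permutation invariant
  expect_identical(select_conformer(select_conformer(cand)), select_conformer(cand))
  expect_identical(select_conformer(cand[2:1, ])$conformer, "sin")

  expect_error(select_conformer(cand[0, ]), "no conformer candidates")
  expect_error(select_conformer(rbind(cand, mk_ddg_row("3", "1", "CDK2", 0))),
               "several")
})

test_that("pair rebasing is exact arithmetic with quadrature errors", {
  d12 <- mk_ddg_row("2", "1", "CDK2", -4, se = 0.3)
  d14 <- mk_ddg_row("4", "1", "CDK2", -3, se = 0.4)
  d24 <- rebase_pair(d12, d14)
  expect_equal(d24$ddG, 1) # ddG(2->4) = -3 - (-4)
  expect_identical(d24$compound_i, "4"); expect_identical(d24$compound_j, "2")
  expect_equal(d24$se, 0.5)

  self <- rebase_pair(d12, d12)
  expect_equal(self$ddG, 0)
  expect_equal(self$se, sqrt(2) * 0.3)

  expect_equal(rebase_pair(d14, d12)$ddG, -rebase_pair(d12, d14)$ddG)

  # cycle consistency over a third compound
  d13 <- mk_ddg_row("3", "1", "CDK2", 2.5, se = 0.2)
  lhs <- rebase_pair(d12, d13)$ddG + rebase_pair(d13, d14)$ddG
  expect_equal(lhs, rebase_pair(d12, d14)$ddG, tolerance = 1e-12)

  expect_error(rebase_pair(d12, mk_ddg_row("4", "1", "CDK1", 0)), "contract")
})

test_that("assemble_ddg builds the full selected grid and reports gaps", {
  # 3 pairs x 4 targets x 3 methods, one conformer -> 36 selected rows
  grid <- expand.grid(pair = c("1->2", "1->3", "1->4"),
                      target = c("CDK1", "CDK2", "CDK5", "CDK9"),
                      method = c("BAR", "CGI", "JAR"),
                      leg = c("complex", "solvent"),
                      stringsAsFactors = FALSE)
  grid$conformer <- "default"
  grid$dG <- seq_len(nrow(grid)); grid$se <- 0.1
  out <- assemble_ddg(grid)
  expect_equal(nrow(out$ddg), 36)
  expect_length(out$diagnostics, 0)
  expect_true(all(out$ddg$selected))

  # a missing solvent leg becomes a diagnostic, not a dropped row
  drop1 <- grid[-which(grid$pair == "1->2" & grid$target == "CDK1" &
                         grid$method == "BAR" & grid$leg == "solvent"), ]
  out2 <- assemble_ddg(drop1)
  expect_equal(nrow(out2$ddg), 35)
  expect_length(out2$diagnostics, 1)
  expect_match(out2$diagnostics, "1->2 | CDK1 | BAR", fixed = TRUE)

  # conformer selection applied per method independently
  extra <- grid[grid$pair == "1->2" & grid$target == "CDK1", ]
  extra$conformer <- "sin"
  extra$dG <- extra$dG - ifelse(extra$leg == "complex", 10, 0) # lower ddG by 10
  two_conf <- rbind(grid, extra)
  out3 <- assemble_ddg(two_conf)
  expect_equal(nrow(out3$ddg), 36)
  sel <- out3$ddg[out3$ddg$compound_i == "2" & out3$ddg$target == "CDK1", ]
  expect_true(all(sel$conformer == "sin")) # lower complex-leg dG wins
})

test_that("a zero-noise synthetic study is recovered through the cycle", {
  spec <- synthetic_study_spec(work_sigma = 0.2, n_forward = 150, n_reverse = 150,
                               ic50_noise_sd = 0, seed = 21)
  study <- make_synthetic_study(spec)
  est <- estimate_study(study$works)
  asm <- assemble_ddg(est)
  m <- merge(asm$ddg, study$truth$ddg, by = c("compound_i", "compound_j", "target"))
  expect_equal(nrow(m), 12 * 3) # 3 pairs x 4 targets x 3 methods
  err <- abs(m$ddG - m$ddG_true)
  # BAR/JAR errors scale as sigma/sqrt(n); the CGI intersection additionally
  # carries variance-estimation noise of order (RT/2) sqrt(2/n), so it gets
  # a correspondingly wider Monte-Carlo band
  expect_lt(max(err[m$method != "CGI"]), 0.15)
  expect_lt(max(err[m$method == "CGI"]), 0.7)
})
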