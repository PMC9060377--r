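rec <- function(iks = 100, vhalf = 100, tau_act = 100, tau_deact = 100) {
  list(iks = iks, vhalf = vhalf, tau_act = tau_act, tau_deact = tau_deact)
}

test_that("criteria bounds classify single-parameter dysfunction", {
  expect_equal(unname(classify_record(rec(iks = 50))), c(1L, 0L, 0L, 0L))
  expect_equal(unname(classify_record(rec())), c(0L, 0L, 0L, 0L))
  expect_equal(unname(classify_record(rec(vhalf = 140))), c(0L, 1L, 0L, 0L))
  expect_equal(unname(classify_record(rec(tau_act = 60))), c(0L, 0L, 1L, 0L))
  expect_equal(unname(classify_record(rec(tau_deact = 130))),
               c(0L, 0L, 0L, 1L))
})

test_that("severe peak-current loss cascades to all four labels", {
  expect_equal(unname(classify_record(rec(iks = 10))), c(1L, 1L, 1L, 1L))
  expect_equal(unname(classify_record(rec(iks = 17))), c(1L, 1L, 1L, 1L))
  # dominance holds whatever the other three values are
  set.seed(7)
  for (i in 1:25) {
    r <- rec(iks = runif(1, 0, 17), vhalf = runif(1, 0, 300),
             tau_act = runif(1, 0, 300), tau_deact = runif(1, 0, 300))
    expect_equal(unname(classify_record(r)), c(1L, 1L, 1L, 1L))
  }
})

test_that("unmeasurable parameters are dysfunctional", {
  expect_equal(unname(classify_record(rec(vhalf = NA, tau_deact = NA))),
               c(0L, 1L, 0L, 1L))
})

test_that("values exactly at a bound are normal (strict inequalities)", {
  expect_equal(unname(classify_record(rec(iks = 55))), c(0L, 0L, 0L, 0L))
  expect_equal(unname(classify_record(rec(iks = 115))), c(0L, 0L, 0L, 0L))
  expect_equal(unname(classify_record(rec(vhalf = 130, tau_act = 170,
                                          tau_deact = 75))),
               c(0L, 0L, 0L, 0L))
})

test_that("classification is pure: same input, same labels", {
  r <- rec(iks = 30, vhalf = NA)
  expect_identical(classify_record(r), classify_record(r))
})

test_that("negative measurements are rejected", {
  expect_error(classify_record(rec(iks = -5)), "negative")
  expect_error(classify_direction(rec(tau_act = -1)), "negative")
})

test_that("direction classes distinguish LOF, GOF and WT-like", {
  expect_equal(unname(classify_direction(rec(iks = 120))["iks"]), "GOF")
  expect_equal(unname(classify_direction(rec())["iks"]), "WT-like")
  expect_equal(unname(classify_direction(rec(iks = NA))["iks"]), "LOF")
  expect_equal(unname(classify_direction(rec(iks = 10))),
               rep("LOF", 4))
  expect_equal(unname(classify_direction(rec(vhalf = 60))["vhalf"]), "GOF")
})

test_that("the narrower activation band is available for ablation", {
  crit <- criteria_table(tau_act_band = c(80, 120))
  expect_equal(unname(classify_record(rec(tau_act = 150), crit)),
               c(0L, 0L, 1L, 0L))
  expect_equal(unname(classify_record(rec(tau_act = 150))),
               c(0L, 0L, 0L, 0L))
})

test_that("variant names parse with trimming and case folding", {
  v <- parse_variant(c("R195Q", " l114p ", "y46C"))
  expect_equal(v$position, c(195L, 114L, 46L))
  expect_equal(v$wt_aa, c("R", "L", "Y"))
  expect_equal(v$mut_aa, c("Q", "P", "C"))
  expect_error(parse_variant("R195X"), "unknown mutant")
  expect_error(parse_variant("195Q"), "unparseable")
  expect_error(parse_variant("R19 5Q"), "unparseable")
})

test_that("the table loader labels rows and reports bad input by row", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("variant,iks,vhalf,tau_act,tau_deact",
               "R195Q,80,140,100,100",
               "G52A,10,100,100,100",
               "T118S,100,100,ND,100",
               "A300E,100,100,100,"), f)
  d <- load_variant_table(f)
  expect_s3_class(d, "kv_dataset")
  expect_equal(nrow(d), 4)
  expect_equal(d$variant, c("R195Q", "G52A", "T118S", "A300E"))
  expect_equal(unname(unlist(d[1, paste0("label_", c("iks", "vhalf",
                                                     "tau_act", "tau_deact"))])),
               c(0L, 1L, 0L, 0L))
  expect_equal(unname(unlist(d[2, grep("^label_", names(d))])), rep(1L, 4))
  expect_true(is.na(d$tau_act[3]))
  expect_equal(d$label_tau_act[3], 1L)   # ND sentinel -> dysfunctional
  expect_equal(d$label_tau_deact[4], 1L) # blank cell -> dysfunctional

  writeLines("variant,iks,vhalf,tau_act,tau_deact", f)
  expect_equal(nrow(load_variant_table(f)), 0)

  writeLines(c("variant,iks,vhalf,tau_act,tau_deact",
               "R195Q,80,140,100,100", "R195Q,90,100,100,100"), f)
  expect_error(load_variant_table(f), "duplicate variant at row 2")

  writeLines(c("variant,iks,vhalf,tau_act,tau_deact",
               "R195X,80,140,100,100"), f)
  expect_error(load_variant_table(f), "unknown mutant")
})

test_that("column mapping adapts to foreign table layouts", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("mutation,peak,v50,act,deact", "R195Q,80,140,100,100"), f)
  d <- load_variant_table(f, col_map = c(variant = "mutation", iks = "peak",
                                         vhalf = "v50", tau_act = "act",
                                         tau_deact = "deact"))
  expect_equal(d$iks, 80)
  expect_equal(d$label_vhalf, 1L)
})

test_that("non-perturbing augmentation yields fully normal records", {
  pos <- data.frame(position = 1:345,
                    wt_aa = rep(c("A", "L", "R", "G", "S"), 69))
  aug <- augment_nonperturbing(pos)
  expect_equal(nrow(aug), 345)
  expect_true(all(aug$wt_aa == aug$mut_aa))
  expect_true(all(label_matrix(aug) == 0L))
  expect_true(all(!aug$is_experimental))
  expect_equal(nrow(augment_nonperturbing(pos[0, ])), 0)
  expect_error(augment_nonperturbing(rbind(pos, pos[1, ])), "unique")
})

test_that("experimental plus augmented records combine to one dataset", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(synthetic_functional_table(7, 2, 4, seed = 5), f,
                   row.names = FALSE, na = "")
  exp_d <- load_variant_table(f)
  aug <- augment_nonperturbing(data.frame(position = 1:20, wt_aa = "A"))
  both <- bind_datasets(exp_d, aug)
  expect_equal(nrow(both), 13 + 20)
  expect_equal(sum(both$is_experimental), 13)
})

test_that("the synthetic functional table realizes its composition", {
  tab <- synthetic_functional_table(7, 2, 4, seed = 42)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE, na = "")
  d <- load_variant_table(f)
  expect_equal(sum(d$dir_iks == "LOF"), 7)
  expect_equal(sum(d$dir_iks == "GOF"), 2)
  expect_equal(sum(d$dir_iks == "WT-like"), 4)
  expect_equal(sum(d$label_iks), 9)
})
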