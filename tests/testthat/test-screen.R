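test_that("drug scores match hand evaluation, identity and bounds", {
  treated <- comp_row(cp = 10, com = 30, d = 20)
  control <- comp_row(cp = 40, com = 10, d = 5)
  expect_equal(differentiating_score(treated, control), 65)

  t2 <- comp_row(q = 30, cm = 20)
  c2 <- comp_row(q = 10, cm = 10)
  expect_equal(dedifferentiating_score(t2, c2), 30)

  expect_identical(differentiating_score(control, control), 0)
  expect_identical(dedifferentiating_score(control, control), 0)

  # bounds of the percentage arithmetic
  expect_equal(differentiating_score(comp_row(d = 100), comp_row(cp = 100)),
               200)
  expect_equal(dedifferentiating_score(comp_row(cp = 100),
                                       comp_row(q = 50, cm = 50)), -100)
})

test_that("scores are antisymmetric and average replicates before scoring", {
  a <- comp_row(q = 10, cm = 5, cp = 30, com = 35, d = 20)
  b <- comp_row(q = 25, cm = 25, cp = 20, com = 20, d = 10)
  expect_equal(differentiating_score(a, b), -differentiating_score(b, a),
               tolerance = 1e-12)
  expect_equal(dedifferentiating_score(a, b), -dedifferentiating_score(b, a),
               tolerance = 1e-12)
  # replicate wells are averaged at the composition level
  reps <- dplyr::bind_rows(comp_row(com = 20, well = "A1"),
                           comp_row(com = 40, well = "A2"))
  expect_equal(differentiating_score(reps, comp_row()), 30)
})

test_that("combined score averages four doses minus the backbone", {
  expect_equal(combined_differentiating_score(c(10, 20, 30, 40), 15), 10)
  expect_equal(combined_differentiating_score(c(0, 0, 0, 0), 0), 0)
  expect_equal(combined_differentiating_score(rep(15, 4), 15), 0)
  expect_error(combined_differentiating_score(c(10, 20), 5),
               class = "myostate_input_error")
  expect_equal(combined_differentiating_score(c(10, 20), 5,
                                              allow_partial = TRUE), 10)
  expect_error(combined_differentiating_score(c(1, 2, 3, 4), NA),
               class = "myostate_input_error")
})

test_that("hit rules follow the strict and at-least-1.5-fold readings", {
  make_screen <- function(treated) {
    dplyr::bind_rows(
      treated,
      comp_row(q = 10, cm = 10, cp = 40, com = 20, d = 5,
               compound = "DMSO", well = "C1", dose = 1)
    ) |> screen_score(control_compound = "DMSO", hit_dose = 1)
  }
  # committed+diff 25 -> 40 and cycling progenitors 40 -> 20: a hit
  res <- make_screen(comp_row(q = 10, cm = 10, cp = 20, com = 30, d = 10,
                              compound = "drug"))
  expect_true(res$is_diff_hit[res$compound == "drug"])
  # cycling progenitors increasing instead: not a hit
  res2 <- make_screen(comp_row(q = 5, cm = 5, cp = 45, com = 30, d = 10,
                               compound = "drug"))
  expect_false(res2$is_diff_hit[res2$compound == "drug"])
  # treated identical to control: strict inequalities fail
  res3 <- make_screen(comp_row(q = 10, cm = 10, cp = 40, com = 20, d = 5,
                               compound = "drug"))
  expect_false(res3$is_diff_hit[res3$compound == "drug"])
  expect_equal(res3$s_diff[res3$compound == "drug"], 0)

  # MuSC 20% -> 40% is a dedifferentiating hit; 1.2-fold is not;
  # exactly 1.5-fold counts ("at least")
  pick_hit <- function(res) res$is_dediff_hit[res$compound == "drug"]
  expect_true(pick_hit(make_screen(comp_row(q = 20, cm = 20, cp = 30,
                                            com = 20, d = 10,
                                            compound = "drug"))))
  expect_false(pick_hit(make_screen(comp_row(q = 12, cm = 12, cp = 40,
                                             com = 26, d = 10,
                                             compound = "drug"))))
  expect_true(pick_hit(make_screen(comp_row(q = 15, cm = 15, cp = 40,
                                            com = 20, d = 10,
                                            compound = "drug"))))
})

test_that("a zero-control MuSC fraction yields an infinite or undefined fold", {
  comp <- dplyr::bind_rows(
    comp_row(q = 10, cm = 0, cp = 40, com = 30, d = 20, compound = "drug"),
    comp_row(q = 0, cm = 0, cp = 50, com = 30, d = 20, compound = "DMSO",
             well = "C1")
  )
  res <- screen_score(comp, hit_dose = 1)
  expect_identical(res$fold_musc[res$compound == "drug"], Inf)
  expect_true(res$is_dediff_hit[res$compound == "drug"])
  comp2 <- dplyr::bind_rows(
    comp_row(q = 0, cm = 0, cp = 50, com = 30, d = 20, compound = "drug"),
    comp_row(q = 0, cm = 0, cp = 50, com = 30, d = 20, compound = "DMSO",
             well = "C1")
  )
  res2 <- screen_score(comp2, hit_dose = 1)
  expect_true(is.na(res2$fold_musc[res2$compound == "drug"]))
  expect_false(res2$is_dediff_hit[res2$compound == "drug"])
})

test_that("screen scoring errors without a plate control", {
  expect_error(screen_score(comp_row(compound = "drug")),
               class = "myostate_input_error")
})

test_that("shared hits are intersected and ranked deterministically", {
  mk <- function(compounds, scores, hits) {
    tibble::tibble(compound = compounds, dose_um = 1, n_wells = 1L,
                   s_diff = scores, s_dediff = scores, fold_musc = 2,
                   is_diff_hit = hits, is_dediff_hit = hits)
  }
  a <- mk(c("x", "y", "z", "w"), c(50, 30, 50, 10),
          c(TRUE, TRUE, TRUE, FALSE))
  b <- mk(c("w", "y", "z"), c(20, 50, 30), c(TRUE, TRUE, TRUE))
  out <- rank_and_intersect(a, b, score = "s_dediff", hit = "is_dediff_hit")
  expect_identical(out$compound, c("y", "z"))
  expect_equal(out$mean_score, c(40, 40))
  expect_identical(out$rank, 1:2)  # tie broken lexicographically
  disjoint <- rank_and_intersect(mk("x", 1, TRUE), mk("y", 1, TRUE))
  expect_identical(nrow(disjoint), 0L)
})

test_that("a planted synthetic screen is fully recovered with clean ranks", {
  sc <- make_screen_layout(n_compounds = 24L, n_diff = 3L, n_dediff = 3L,
                           n_cells = 2000L)
  cfg <- sim_config(seed = 61, plate_layout = sc$layout)
  sim <- simulate_plate(cfg)
  bg <- estimate_background(sim$cells[sim$cells$well == "H12", ])
  stained <- sim$cells[sim$cells$well != "H12", ]
  comp <- compose_wells(gate_cells(stained, bg))
  res <- screen_score(comp, control_compound = "DMSO", hit_dose = 1,
                      margin = 5)
  hits_diff <- res$compound[!is.na(res$is_diff_hit) & res$is_diff_hit]
  hits_dediff <- res$compound[!is.na(res$is_dediff_hit) & res$is_dediff_hit]
  expect_setequal(hits_diff, sc$planted_diff)
  expect_setequal(hits_dediff, sc$planted_dediff)
  ranked <- res[!is.na(res$is_diff_hit), ]
  ranked <- ranked[order(-ranked$s_diff), ]
  expect_setequal(ranked$compound[seq_along(sc$planted_diff)],
                  sc$planted_diff)
})
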