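two_pop_fixture <- function() {
  facilities <- data.frame(id = "f1", x = 0, y = 0, capacity = 10,
                           stringsAsFactors = FALSE)
  populations <- data.frame(id = c("p1", "p2"), x = 0, y = 0,
                            population = c(2000, 4000),
                            stringsAsFactors = FALSE)
  od <- od_matrix(data.frame(facility_id = "f1",
                             population_id = c("p1", "p2"),
                             minutes = c(5, 10)),
                  facilities$id, populations$id)
  list(facilities = facilities, populations = populations, od = od)
}

test_that("facility FPR sums unweighted population within the window", {
  fx <- two_pop_fixture()
  expect_equal(facility_fpr(fx$facilities, fx$populations, fx$od, 5),
               10 / 2000)
  expect_equal(facility_fpr(fx$facilities, fx$populations, fx$od, 10),
               10 / 6000, tolerance = 1e-7)
  expect_identical(facility_fpr(fx$facilities, fx$populations, fx$od, 1),
                   SENTINEL_INF)
})

test_that("facility catchment stops at the first grid time meeting the threshold", {
  fx <- two_pop_fixture()
  cfg <- ev_config(t0 = 5, dt = 1, fprt1 = 0.0027)
  # 10/2000 = 0.005 > 0.0027 for t in 5..9; 10/6000 at t = 10
  res <- facility_catchment(fx$facilities, fx$populations, fx$od, cfg)
  expect_equal(res$catchment, 10)
  expect_equal(res$fpr, 10 / 6000, tolerance = 1e-7)
  expect_false(res$capped)

  rich <- fx
  rich$populations$population <- c(5000, 0)
  res2 <- facility_catchment(rich$facilities, rich$populations, fx$od, cfg)
  expect_equal(res2$catchment, 5)   # 0.002 <= 0.0027 already at t0

  empty <- fx
  empty$populations$population <- c(0, 0)
  res3 <- facility_catchment(empty$facilities, empty$populations, fx$od,
                             cfg)
  expect_equal(res3$catchment, 120)
  expect_true(res3$capped)
  expect_identical(res3$fpr, SENTINEL_INF)
})

test_that("population catchment accumulates saved facility ratios", {
  pop <- data.frame(id = "p1", x = 0, y = 0, population = 1000)
  fprs <- data.frame(facility_id = c("f1", "f2"), fpr = c(0.01, 0.025),
                     stringsAsFactors = FALSE)
  od <- od_matrix(data.frame(facility_id = c("f1", "f2"),
                             population_id = "p1", minutes = c(5, 12)),
                  fprs$facility_id, pop$id)
  cfg <- ev_config(t0 = 5, dt = 1, fprt2 = 0.03)
  # 0.01 < 0.03 for t in 5..11; 0.035 >= 0.03 at t = 12
  expect_equal(population_catchment(pop, fprs, od, cfg)$catchment, 12)

  one <- data.frame(facility_id = "f1", fpr = 0.05)
  od1 <- od_matrix(data.frame(facility_id = "f1", population_id = "p1",
                              minutes = 5), "f1", pop$id)
  expect_equal(population_catchment(pop, one, od1, cfg)$catchment, 5)

  far <- od_matrix(data.frame(facility_id = "f1", population_id = "p1",
                              minutes = 300), "f1", pop$id, t_max = 120)
  res <- population_catchment(pop, one, far, cfg)
  expect_equal(res$catchment, 120)
  expect_true(res$capped)

  # an Inf sentinel ratio satisfies the target as soon as it is in range
  inf_fpr <- data.frame(facility_id = "f1", fpr = Inf)
  expect_equal(population_catchment(pop, inf_fpr, od1, cfg)$catchment, 5)
})

test_that("V2SFCA supply catchment meets the base population, not a ratio", {
  fac <- data.frame(id = "f1", x = 0, y = 0, capacity = 77)
  pops <- data.frame(id = c("p1", "p2"), x = 0, y = 0,
                     population = c(4000, 6000), stringsAsFactors = FALSE)
  od <- od_matrix(data.frame(facility_id = "f1",
                             population_id = c("p1", "p2"),
                             minutes = c(5, 20)), fac$id, pops$id)
  cfg <- v2_config(base_population = 5000, t0 = 5, dt = 1)
  res <- v2sfca_supply_catchment(fac, pops, od, cfg)
  expect_equal(res$catchment, 20)
  expect_equal(res$ratio, 77 / 10000)
  expect_false(res$capped)

  near <- pops; near$population <- c(6000, 0)
  expect_equal(v2sfca_supply_catchment(fac, near, od, cfg)$catchment, 5)

  sparse <- pops; sparse$population <- c(1000, 2000)
  res2 <- v2sfca_supply_catchment(fac, sparse, od, cfg)
  expect_equal(res2$catchment, 120)
  expect_true(res2$capped)
  expect_equal(res2$ratio, 77 / 3000)
})

test_that("V2SFCA demand catchment accumulates supply ratios to the PPR", {
  pop <- data.frame(id = "p1", x = 0, y = 0, population = 1000)
  ratios <- data.frame(facility_id = c("f1", "f2"),
                       ratio = c(0.01, 0.025), stringsAsFactors = FALSE)
  od <- od_matrix(data.frame(facility_id = c("f1", "f2"),
                             population_id = "p1", minutes = c(5, 12)),
                  ratios$facility_id, pop$id)
  cfg <- v2_config(ppr = 0.03, t0 = 5, dt = 1)
  expect_equal(v2sfca_demand_catchment(pop, ratios, od, cfg)$catchment, 12)

  strong <- data.frame(facility_id = "f1", ratio = 0.05)
  od1 <- od_matrix(data.frame(facility_id = "f1", population_id = "p1",
                              minutes = 5), "f1", pop$id)
  expect_equal(v2sfca_demand_catchment(pop, strong, od1, cfg)$catchment, 5)

  none <- od_matrix(data.frame(facility_id = "f1", population_id = "p1",
                               minutes = 500), "f1", pop$id, t_max = 120)
  res <- v2sfca_demand_catchment(pop, strong, none, cfg)
  expect_equal(res$catchment, 120)
  expect_true(res$capped)
})

test_that("batch catchments match the worked instance and per-site operations", {
  fx <- toy_instance()
  ct <- compute_all_catchments(fx$facilities, fx$populations, fx$od,
                               fx$cfg, "ev2sfca")
  expect_equal(ct$catchment_min, c(20, 5, 120, 120))
  expect_equal(ct$capped, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(ct$fpr[1:2], c(0.0025, 10 / 6000), tolerance = 1e-9)

  set.seed(11)
  for (k in 1:10) {
    inst <- random_instance()
    ct <- suppressWarnings(
      compute_all_catchments(inst$facilities, inst$populations, inst$od,
                             inst$cfg, "ev2sfca"))
    for (i in seq_len(nrow(inst$facilities))) {
      per <- facility_catchment(inst$facilities[i, ], inst$populations,
                                inst$od, inst$cfg)
      row <- ct[ct$id == inst$facilities$id[i], ]
      expect_equal(row$catchment_min, per$catchment)
      expect_equal(row$fpr, per$fpr)
      expect_equal(row$capped, per$capped)
    }
    fprs <- data.frame(facility_id = ct$id[ct$type == "facility"],
                       fpr = ct$fpr[ct$type == "facility"])
    for (j in seq_len(nrow(inst$populations))) {
      per <- population_catchment(inst$populations[j, ], fprs, inst$od,
                                  inst$cfg)
      row <- ct[ct$id == inst$populations$id[j], ]
      expect_equal(row$catchment_min, per$catchment)
      expect_equal(row$capped, per$capped)
    }
  }
})

test_that("degenerate inputs: no facilities, co-located pair, id mismatch", {
  pops <- data.frame(id = c("p1", "p2"), x = 0, y = 0,
                     population = c(10, 20), stringsAsFactors = FALSE)
  fac0 <- data.frame(id = character(0), x = numeric(0), y = numeric(0),
                     capacity = numeric(0), stringsAsFactors = FALSE)
  od0 <- as_od_matrix(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, pops$id)))
  ct <- compute_all_catchments(fac0, pops, od0, ev_config(), "ev2sfca")
  expect_equal(nrow(ct), 2)
  expect_true(all(ct$capped))
  expect_true(all(ct$catchment_min == 120))

  fac <- data.frame(id = "f1", x = 0, y = 0, capacity = 10)
  pop <- data.frame(id = "p1", x = 0, y = 0, population = 5000)
  od <- od_matrix(data.frame(facility_id = "f1", population_id = "p1",
                             minutes = 0), "f1", "p1")
  ct2 <- compute_all_catchments(fac, pop, od, ev_config(), "ev2sfca")
  expect_equal(ct2$catchment_min[ct2$type == "facility"], 5)  # met at t0

  expect_error(
    compute_all_catchments(fac, pops, od, ev_config(), "ev2sfca"),
    "id mismatch")
})

test_that("every catchment sits on the search grid and brackets its threshold", {
  set.seed(23)
  for (k in 1:25) {
    inst <- random_instance()
    cfg <- inst$cfg
    ct <- suppressWarnings(
      compute_all_catchments(inst$facilities, inst$populations, inst$od,
                             cfg, "ev2sfca"))
    expect_true(all(ct$catchment_min >= cfg$t0 &
                    ct$catchment_min <= cfg$t_max))
    # capped searches stop at t_max by the cap rule even when t_max is
    # off-grid; every uncapped catchment must sit on the search grid
    on_grid <- (ct$catchment_min[!ct$capped] - cfg$t0) %% cfg$dt
    expect_true(all(abs(on_grid) < 1e-9 | abs(on_grid - cfg$dt) < 1e-9))
    fc <- ct[ct$type == "facility", ]
    for (i in seq_len(nrow(fc))) {
      if (fc$capped[i]) next
      C <- fc$catchment_min[i]
      fac <- inst$facilities[inst$facilities$id == fc$id[i], ]
      expect_true(facility_fpr(fac, inst$populations, inst$od, C) <=
                  cfg$fprt1)
      if (C > cfg$t0)
        expect_true(facility_fpr(fac, inst$populations, inst$od,
                                 C - cfg$dt) > cfg$fprt1)
    }
  }
})

test_that("catchments respond monotonically to capacity, demand and thresholds", {
  set.seed(31)
  for (k in 1:10) {
    inst <- random_instance(nf = 3, np = 4)
    base <- suppressWarnings(
      compute_all_catchments(inst$facilities, inst$populations, inst$od,
                             inst$cfg, "ev2sfca"))
    # more beds never shrink a facility catchment
    bigger <- inst$facilities
    bigger$capacity <- bigger$capacity * 3
    up <- suppressWarnings(
      compute_all_catchments(bigger, inst$populations, inst$od, inst$cfg,
                             "ev2sfca"))
    expect_true(all(up$catchment_min[up$type == "facility"] >=
                    base$catchment_min[base$type == "facility"]))
    # more demand never grows one
    denser <- inst$populations
    denser$population <- denser$population + 500
    dn <- suppressWarnings(
      compute_all_catchments(inst$facilities, denser, inst$od, inst$cfg,
                             "ev2sfca"))
    expect_true(all(dn$catchment_min[dn$type == "facility"] <=
                    base$catchment_min[base$type == "facility"]))
    # smaller fprt1 never shrinks facility catchments
    tight <- inst$cfg
    tight$fprt1 <- inst$cfg$fprt1 / 4
    tg <- suppressWarnings(
      compute_all_catchments(inst$facilities, inst$populations, inst$od,
                             tight, "ev2sfca"))
    expect_true(all(tg$catchment_min[tg$type == "facility"] >=
                    base$catchment_min[base$type == "facility"]))
    # larger fprt2 never shrinks population catchments
    want <- inst$cfg
    want$fprt2 <- inst$cfg$fprt2 * 4
    wt <- suppressWarnings(
      compute_all_catchments(inst$facilities, inst$populations, inst$od,
                             want, "ev2sfca"))
    expect_true(all(wt$catchment_min[wt$type == "population"] >=
                    base$catchment_min[base$type == "population"]))
  }
})

test_that("V2SFCA supply catchments ignore capacity while EV2SFCA reacts to it", {
  fx <- two_pop_fixture()
  v2 <- v2_config(base_population = 3000, t0 = 5, dt = 1)
  base <- v2sfca_supply_catchment(fx$facilities, fx$populations, fx$od, v2)
  huge <- fx$facilities
  huge$capacity <- 10000
  again <- v2sfca_supply_catchment(huge, fx$populations, fx$od, v2)
  expect_identical(base$catchment, again$catchment)

  cfg <- ev_config(t0 = 5, dt = 1, fprt1 = 0.0027)
  ev_small <- facility_catchment(fx$facilities, fx$populations, fx$od, cfg)
  ev_large <- facility_catchment(huge, fx$populations, fx$od, cfg)
  expect_true(ev_large$catchment > ev_small$catchment)
})
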