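# carbonate constants and speciation solver

test_that("constant set obeys its structural invariants", {
  k <- carb_constants(18, 35)
  vals <- unlist(k[c("K0", "K1", "K2", "KB", "Kw", "Ksp_arag", "BT", "Ca")])
  expect_true(all(vals > 0))
  expect_gt(k$K1, k$K2)
  # K0 strictly decreasing in T at fixed S
  k0 <- vapply(seq(0, 30, by = 5), function(tc) carb_constants(tc, 35)$K0,
               numeric(1))
  expect_true(all(diff(k0) < 0))
  expect_gt(carb_constants(3, 35)$K0, carb_constants(30, 35)$K0)
  # BT and Ca proportional to S
  k20 <- carb_constants(18, 20)
  expect_equal(k$BT / k20$BT, 35 / 20, tolerance = 1e-12)
  expect_equal(k$Ca / k20$Ca, 35 / 20, tolerance = 1e-12)
})

test_that("out-of-range conditions raise domain errors naming the value", {
  expect_error(carb_constants(45, 35), "temperature.*45")
  expect_error(carb_constants(18, -1), "salinity.*-1")
  expect_error(carb_constants(18, 50), "salinity.*50")
  expect_error(carb_solve(2000, 2300, 18, 35, phosphate = -1), "nutrient")
  expect_error(carb_solve_pco2(400, 2300, 18, 35, silicate = -2), "nutrient")
})

test_that("constants agree with the independent oracle within 0.5%", {
  for (tc in c(5, 18, 25)) {
    k <- carb_constants(tc, 35)
    o <- oracle_constants(tc, 35)
    expect_equal(k$K0, o$k0, tolerance = 0.005)
    expect_equal(k$K1, o$k1, tolerance = 0.005)
    expect_equal(k$K2, o$k2, tolerance = 0.005)
  }
})

test_that("reference state solves to the documented anchor", {
  st <- carb_solve_pco2(395, 2280, 18, 35)
  expect_equal(st$dic, 2038.6, tolerance = 0.5 / 2038.6)
  # and the reverse direction reproduces pCO2 = 395 +- 1
  st2 <- carb_solve(2038.6, 2280, 18, 35)
  expect_lt(abs(st2$pco2 - 395), 1)
})

test_that("CO2 addition at fixed TA is monotone; cold water holds more DIC", {
  lo <- carb_solve_pco2(395, 2280, 18, 35)
  hi <- carb_solve_pco2(790, 2280, 18, 35)
  expect_gt(hi$dic, lo$dic)
  expect_lt(hi$omega_arag, lo$omega_arag)
  expect_lt(hi$ph, lo$ph)
  cold <- carb_solve_pco2(395, 2280, 3, 35)
  expect_gt(cold$dic, lo$dic)
  # exact cold-water value cross-checked against the oracle
  o <- oracle_solve_dic_ta(cold$dic, 2280, 3, 35)
  expect_lt(abs(o$pco2 - 395), 1)
})

test_that("a state with [CO2] = [CO3] sits exactly at -0.5 log10(K1 K2)", {
  k <- carb_constants(10, 35)
  # H where CO2 = CO3: H^2 = K1 K2 (from the two dissociation steps)
  h <- sqrt(k$K1 * k$K2)
  dic_u <- 2100
  # assemble the implied TA and solve back
  dic <- dic_u * 1e-6
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  ca_alk <- dic * (k$K1 * h + 2 * k$K1 * k$K2) / denom
  ta_u <- (ca_alk + coastcarb:::.alk_minor(h, k, 0, 0)) * 1e6
  st <- carb_solve(dic_u, ta_u, 10, 35)
  expect_equal(st$ph, -0.5 * log10(k$K1 * k$K2), tolerance = 1e-6)
  expect_equal(st$co2, st$co3, tolerance = 1e-6)
})

test_that("solved states close their alkalinity balance below 1e-9 mol/kg", {
  grid <- expand.grid(t = c(0, 10, 20, 30), s = c(20, 30, 37),
                      ta = c(2000, 2280, 2450))
  for (i in seq_len(nrow(grid))) {
    st <- carb_solve(0.92 * grid$ta[i], grid$ta[i], grid$t[i], grid$s[i])
    expect_lt(abs(alk_residual(st)), 1e-9)
  }
  # with nutrients too
  st <- carb_solve(2050, 2300, 12, 33, phosphate = 1.5, silicate = 20)
  expect_lt(abs(alk_residual(st)), 1e-9)
})

test_that("input-pair round trips are mutually consistent", {
  grid <- expand.grid(t = c(0, 15, 30), s = c(20, 30, 37),
                      ta = c(2000, 2200, 2450))
  for (i in seq_len(nrow(grid))) {
    dic <- 0.93 * grid$ta[i]
    a <- carb_solve(dic, grid$ta[i], grid$t[i], grid$s[i])
    b <- carb_solve_pco2(a$pco2, grid$ta[i], grid$t[i], grid$s[i])
    expect_lt(abs(b$dic - dic), 1e-3)
    c_ <- carb_solve_ph(a$ph, grid$ta[i], grid$t[i], grid$s[i])
    expect_lt(abs(c_$dic - dic), 1e-3)
    expect_lt(abs(b$ph - a$ph), 1e-5)
  }
})

test_that("DIC decomposes into its three species and omega tracks CO3", {
  st <- carb_solve(c(1900, 2000, 2100), 2280, 18, 35)
  expect_equal(st$co2 + st$hco3 + st$co3, st$dic, tolerance = 1e-9)
  expect_true(all(diff(st$co3) < 0))
  expect_true(all(diff(st$omega_arag) < 0))
  expect_equal(order(st$omega_arag), order(st$co3))
  expect_true(all(st$co2 > 0 & st$hco3 > 0 & st$co3 > 0))
})

test_that("preconditions on DIC, TA and the DIC/TA ratio are enforced", {
  expect_error(carb_solve(-5, 2280, 18, 35), "positive")
  expect_error(carb_solve(2000, -1, 18, 35), "positive")
  expect_error(carb_solve(500, 2280, 18, 35), "DIC/TA")
  expect_error(carb_solve(3000, 2280, 18, 35), "DIC/TA")
  expect_error(carb_solve_pco2(-10, 2280, 18, 35), "positive")
})

test_that("solver is deterministic and vectorises consistently", {
  a <- carb_solve(2038.6, 2280, 18, 35)
  b <- carb_solve(2038.6, 2280, 18, 35)
  expect_identical(a, b)
  v <- carb_solve(c(2000, 2038.6), c(2250, 2280), c(10, 18), 35)
  one <- carb_solve(2038.6, 2280, 18, 35)
  expect_equal(v$ph[2], one$ph)
})
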