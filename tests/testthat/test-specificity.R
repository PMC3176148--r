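test_that("internal-standard concentrations follow the spiked amounts", {
  std <- internal_standard_set()
  # 10 ug of 7:0 (MW 130.185) in 2 mL -> 38.41 nmol/mL
  expect_equal(unname(std$conc_nmol_ml["7:0"]), 10 / 130.185 * 1000 / 2,
               tolerance = 1e-12)
  expect_equal(round(unname(std$conc_nmol_ml["7:0"]), 2), 38.41)
  expect_error(internal_standard_set(mass_ug = c("7:0" = -1, "11:0" = 10,
                                                 "17:0" = 20)))
})

test_that("quantify maps analytes to the carbon-range standard", {
  # distinct IS areas so wrong assignment would change the answer
  peaks <- data.frame(
    species = c("7:0", "11:0", "17:0", "8:0", "12:0", "14:0", "4:0",
                "9:0", "10:0", "13:0", "2-tridecanone"),
    area = c(1000, 2000, 4000, 1000, 1000, 1000, 500, 500, 500, 500, 400))
  std <- internal_standard_set()
  conc <- quantify(peaks, std)
  c7 <- unname(std$conc_nmol_ml["7:0"])
  c11 <- unname(std$conc_nmol_ml["11:0"])
  c17 <- unname(std$conc_nmol_ml["17:0"])
  expect_equal(unname(conc["8:0"]), 1000 / 1000 * c7, tolerance = 1e-12)
  expect_equal(unname(conc["12:0"]), 1000 / 2000 * c11, tolerance = 1e-12)
  expect_equal(unname(conc["14:0"]), 1000 / 4000 * c17, tolerance = 1e-12)
  expect_equal(unname(conc["4:0"]), 500 / 1000 * c7, tolerance = 1e-12)
  # C9 maps to the 7:0 standard; C13 (and the C13 methylketone) to 17:0
  expect_equal(unname(conc["9:0"]), 500 / 1000 * c7, tolerance = 1e-12)
  expect_equal(unname(conc["13:0"]), 500 / 4000 * c17, tolerance = 1e-12)
  expect_equal(unname(conc["2-tridecanone"]), 400 / 4000 * c17,
               tolerance = 1e-12)
  # zero area -> zero concentration
  pk0 <- rbind(peaks, data.frame(species = "6:0", area = 0))
  expect_equal(unname(quantify(pk0, std)["6:0"]), 0)
})

test_that("quantify is linear in analyte area and inverse in IS area", {
  base <- data.frame(species = c("7:0", "11:0", "17:0", "8:0"),
                     area = c(1000, 1000, 1000, 800))
  std <- internal_standard_set()
  c1 <- quantify(base, std)["8:0"]
  dbl <- base; dbl$area[4] <- 1600
  expect_equal(unname(quantify(dbl, std)["8:0"]), 2 * unname(c1),
               tolerance = 1e-12)
  half_is <- base; half_is$area[1] <- 2000
  expect_equal(unname(quantify(half_is, std)["8:0"]), unname(c1) / 2,
               tolerance = 1e-12)
  # response factors scale linearly
  rf <- quantify(base, std, response_factors = c("8:0" = 1.5))["8:0"]
  expect_equal(unname(rf), 1.5 * unname(c1), tolerance = 1e-12)
})

test_that("quantify errors on missing or empty internal standards", {
  std <- internal_standard_set()
  expect_error(quantify(data.frame(species = c("7:0", "11:0", "8:0"),
                                   area = c(1, 1, 1)), std), "17:0")
  expect_error(quantify(data.frame(species = c("7:0", "11:0", "17:0"),
                                   area = c(1, 0, 1)), std), "zero.*11:0")
  expect_error(carbon_number("nonsense"), "unparseable")
})

test_that("background subtraction nets out the control strain", {
  sample <- c("8:0" = 10.0, "14:0" = 1.0, "10:0" = 5.0)
  control <- c("8:0" = 2.0, "14:0" = 3.5, "16:0" = 3.1)
  net <- background_subtract(sample, control)
  expect_equal(unname(net["8:0"]), 8.0)
  expect_equal(unname(net["14:0"]), 0)          # clamped
  expect_equal(unname(net["16:0"]), 0)
  expect_equal(unname(net["10:0"]), 5.0)
  expect_setequal(attr(net, "clamped"), c("14:0", "16:0"))
  # all-zero control is the identity
  net2 <- background_subtract(sample, c("8:0" = 0))
  expect_equal(net2[names(sample)], sample, ignore_attr = TRUE)
})

test_that("profiles express mol% of the fatty-acid total", {
  prof <- compose_profile(c("8:0" = 50, "10:0" = 25, "14:0" = 25), "enzA")
  expect_equal(unname(prof$mol_percent[c("8:0", "10:0", "14:0")]),
               c(50, 25, 25))
  expect_equal(prof$total_fa, 100)
  expect_equal(sum(prof$mol_percent), 100, tolerance = 1e-9)
  # methylketones sit outside the mol% denominator
  prof2 <- compose_profile(c("8:0" = 100, "14:0" = 200,
                             "2-tridecanone" = 9.4), "enzB")
  expect_equal(prof2$total_fa, 300)
  expect_equal(unname(prof2$methylketone_molpct["2-tridecanone"]),
               100 * 9.4 / 300, tolerance = 1e-12)
  expect_equal(sum(prof2$mol_percent), 100, tolerance = 1e-9)
  expect_error(compose_profile(c("8:0" = 0), "enzC"), "no activity")
})

test_that("noise-free synthetic peak tables invert through the pipeline", {
  sim <- simulate_profiles(concentration = Inf, total_sdlog = 0, seed = 2)
  control <- setNames(sim$control$nmol_per_mL, sim$control$species)
  profs <- lapply(split(sim$peaks, sim$peaks$enzyme), function(tab) {
    conc <- quantify(tab[, c("species", "area")], sim$standards)
    compose_profile(background_subtract(conc, control), tab$enzyme[1])
  })
  X <- profiles_matrix(profs)
  expect_equal(X[rownames(sim$molpct), colnames(sim$molpct)], sim$molpct,
               tolerance = 1e-9)
  sums <- rowSums(X)
  expect_equal(unname(sums), rep(100, nrow(X)), tolerance = 1e-9)
})

test_that("profile CSV writer emits net concentrations and mol%", {
  prof <- compose_profile(c("8:0" = 75, "14:0" = 25), "enzA")
  path <- withr::local_tempfile(fileext = ".csv")
  tot <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(list(prof), path, tot)
  tab <- read.csv(path)
  expect_equal(tab$mol_pct[tab$species == "8:0"], 75)
  expect_equal(read.csv(tot)$total_fa_nmol_per_mL, 100)
})
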