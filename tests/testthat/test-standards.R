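tissue_df <- function(cultivar, seeds) {
  data.frame(cultivar = cultivar,
             do.call(rbind, lapply(seeds, function(s)
               as.data.frame(t(setNames(random_concentrations(s),
                                        paste0("tissue_", tolower(onion_parts()))))))))
}

test_that("standards derivation per cultivar, with minimum-count handling", {
  tn <- rbind(tissue_df("A", 1:10), tissue_df("B", 11:14), tissue_df("C", 15))
  expect_warning(st <- derive_standards(tn), "C")
  expect_setequal(names(st$standards), c("A", "B"))
  expect_equal(st$standards$A$n, 10)
  expect_equal(st$provenance$tn_counts$A, 10)
  # centroid closes to kappa for every cultivar
  for (s in st$standards)
    expect_equal(sum(composition_parts(s$centroid)), 1000)
  expect_error(suppressWarnings(derive_standards(tissue_df("C", 15))),
               "empty standards")

  # identical specimens: centroid equals the composition, degenerate flag
  one <- tissue_df("A", c(3, 3, 3))
  expect_warning(st1 <- derive_standards(one), "insufficient variance")
  expect_true(st1$standards$A$degenerate)
  expect_equal(composition_parts(st1$standards$A$centroid),
               composition_parts(random_composition(3)), tolerance = 1e-9)
})

test_that("standards recover known generating centers", {
  cfg <- generator_config(seed = 601)
  # at n = 500/cultivar the centroid error stays under 2% part-wise
  for (cv in names(cfg$clr_centers)) {
    tis <- generate_tissue(cv, 500, cfg, seed = derive_seed(601, cv))
    st <- fit_standard(lapply(tis, clr_transform), cv)
    ctr <- cfg$clr_centers[[cv]]; ctr <- ctr - mean(ctr)
    tc <- composition_parts(suppressWarnings(clr_back_transform(ctr)))
    gc <- composition_parts(st$centroid)
    expect_true(all(abs(gc - tc) / tc < 0.02), label = cv)
  }
  # at n = 200 the clr means sit within 3 standard errors of truth
  for (cv in names(cfg$clr_centers)) {
    tis <- generate_tissue(cv, 200, cfg, seed = derive_seed(602, cv))
    st <- fit_standard(lapply(tis, clr_transform), cv)
    ctr <- cfg$clr_centers[[cv]]; ctr <- ctr - mean(ctr)
    expect_true(all(abs(st$clr_mean - ctr) < 3 * st$clr_sd / sqrt(200)),
                label = cv)
  }
})

test_that("concentration quartiles use linear interpolation", {
  tn <- tissue_df("A", 1:4)
  tn$tissue_n <- c(1, 2, 3, 4)
  q <- concentration_quartiles(tn)
  expect_equal(q$lq[q$nutrient == "N"], 1.75)
  expect_equal(q$hq[q$nutrient == "N"], 3.25)
  expect_true(all(q$lq <= q$hq))
  # constant column collapses to lq = hq
  tn$tissue_mg <- 3
  q2 <- concentration_quartiles(tn)
  expect_equal(q2$lq[q2$nutrient == "Mg"], q2$hq[q2$nutrient == "Mg"])
  # too few specimens -> cultivar skipped
  expect_warning(q3 <- concentration_quartiles(rbind(tn, tissue_df("B", 5:7))),
                 "B")
  expect_false("B" %in% q3$cultivar)
})

test_that("diagnosis applies the sign/threshold rule and finds neighbours", {
  tn <- tissue_df("A", 1:15)
  st <- derive_standards(tn)
  centroid <- st$standards$A$centroid
  bank <- lapply(1:15, function(s) random_clr(s))
  bank <- c(bank, list(clr_transform(centroid)))

  d <- diagnose(centroid, st, "A", reference_bank = bank, k = 3)
  expect_true(all(d$verdict == "balanced"))
  expect_equal(d$neighbors$epsilon[1], 0)
  expect_equal(d$neighbors$index[1], 16)

  # +2 SD on S in clr space -> excess verdict for S
  v <- st$standards$A$clr_mean
  v["S"] <- v["S"] + 2 * st$standards$A$clr_sd["S"]
  d2 <- diagnose(structure(v, class = "clr_vector"), st, "A")
  expect_identical(unname(d2$verdict["S"]), "excess")

  # independent loop oracle on random specimens
  for (s in 101:105) {
    sp <- random_clr(s)
    d3 <- diagnose(sp, st, "A", index_threshold = 0.8)
    brute <- ifelse(d3$indices > 0.8, "excess",
             ifelse(d3$indices < -0.8, "shortage", "balanced"))
    expect_identical(d3$verdict, brute)
  }
  expect_error(diagnose(centroid, st, "Nope"), "available")
})

test_that("standards from disjoint halves of one pool agree within 3 pooled SEs", {
  cfg <- generator_config(seed = 640)
  tis <- generate_tissue("Omega", 400, cfg, seed = 641)
  conc <- do.call(rbind, lapply(tis, function(c)
    as.data.frame(t(setNames(c$concentrations,
                             paste0("tissue_", tolower(onion_parts())))))))
  pool <- data.frame(cultivar = "Omega", conc)
  a <- derive_standards(pool[1:200, ])$standards$Omega
  b <- derive_standards(pool[201:400, ])$standards$Omega
  se <- sqrt(a$clr_sd^2 / a$n + b$clr_sd^2 / b$n)
  expect_true(all(abs(a$clr_mean - b$clr_mean) < 3 * se))
})
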