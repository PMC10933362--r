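test_that("closure computes the filling value and rejects bad input", {
  conc <- setNames(rep(100 / 11, 11), onion_parts())
  comp <- close_composition(conc)
  expect_equal(comp$fv, 900)
  expect_equal(sum(composition_parts(comp)), 1000)

  # published Caeté centroid row closes to the printed filling value
  caete <- setNames(c(30.7, 4.3, 25.7, 10.1, 3.3, 7.7, 0.038, 0.034, 0.063,
                      0.129, 0.066), onion_parts())
  expect_equal(close_composition(caete)$fv, 917.9, tolerance = 0.1 / 917.9)

  bad <- conc; bad["Zn"] <- 0
  expect_error(close_composition(bad), "Zn")
  expect_error(close_composition(conc, kappa = 50), "closure violation")
  expect_error(close_composition(conc * -1), "non-positive")
})

test_that("clr transform centers on the geometric mean and sums to zero", {
  # equal parts map to the zero vector
  comp <- close_composition(setNames(rep(83, 11), onion_parts()), kappa = 996)
  expect_equal(unclass(clr_transform(comp)), setNames(rep(0, 12),
               onion_parts(with_fv = TRUE)), tolerance = 1e-12)

  # equals the mean of pairwise log ratios, by explicit double loop
  comp <- random_composition(11)
  x <- composition_parts(comp)
  v <- unclass(clr_transform(comp))
  brute <- vapply(seq_along(x), function(i)
    mean(vapply(seq_along(x), function(j) log(x[i] / x[j]), numeric(1))),
    numeric(1))
  expect_equal(unname(v), unname(brute), tolerance = 1e-12)

  for (s in 1:20)
    expect_lt(abs(sum(unclass(random_clr(s)))), 1e-9)
})

test_that("back-transform inverts the clr and closes to kappa", {
  for (s in 1:10) {
    comp <- random_composition(s)
    back <- clr_back_transform(clr_transform(comp), kappa = comp$kappa)
    expect_equal(composition_parts(back), composition_parts(comp),
                 tolerance = 1e-9)
  }
  # all-zero clr -> uniform composition
  uni <- clr_back_transform(clr_vector(rep(0, 12)))
  expect_equal(unname(composition_parts(uni)), rep(1000 / 12, 12))
  # offset input is absorbed by closure, with a warning
  v <- unclass(random_clr(3))
  expect_warning(shifted <- clr_back_transform(v + 0.5), "closure absorbs")
  expect_equal(composition_parts(shifted),
               composition_parts(clr_back_transform(v)), tolerance = 1e-9)
  expect_error(clr_back_transform(c(v[-1], NA)), "finite")
})

test_that("clr distance is the Euclidean metric", {
  a <- random_clr(1); b <- random_clr(2); c_ <- random_clr(3)
  expect_equal(clr_distance(a, a), 0)
  expect_equal(clr_distance(a, b), clr_distance(b, a))
  expect_equal(clr_distance(a, b),
               sqrt(sum(vapply(seq_along(a), function(k)
                 (unclass(a)[k] - unclass(b)[k])^2, numeric(1)))))
  # Pythagorean case
  x <- clr_vector(c(1, -1, rep(0, 10)))
  y <- clr_vector(rep(0, 12))
  expect_equal(clr_distance(x, y), sqrt(2))
  # triangle inequality on random triples
  for (s in 1:25) {
    p <- random_clr(s); q <- random_clr(s + 100); r <- random_clr(s + 200)
    expect_lte(clr_distance(p, r), clr_distance(p, q) + clr_distance(q, r) + 1e-12)
  }
  expect_error(clr_distance(unclass(a)[1:5], unclass(b)), "incompatible")
})

test_that("fit_standard estimates means, SDs and t-intervals", {
  specs <- lapply(1:30, function(s) random_clr(s))
  st <- fit_standard(specs, "X", alpha = 0.01)
  m <- do.call(rbind, lapply(specs, unclass))
  expect_equal(unname(st$clr_mean), unname(colMeans(m)))
  expect_equal(unname(st$clr_sd), unname(apply(m, 2, sd)))
  half <- qt(0.995, 29) * apply(m, 2, sd) / sqrt(30)
  expect_equal(unname(st$ci_high - st$clr_mean), unname(half))
  expect_true(all(st$ci_low < st$clr_mean & st$clr_mean < st$ci_high))
  expect_lt(abs(sum(st$clr_mean)), 1e-9)
  expect_equal(sum(composition_parts(st$centroid)), 1000)

  # degenerate sample: identical specimens
  same <- rep(list(random_clr(7)), 4)
  expect_warning(st0 <- fit_standard(same, "X"), "insufficient variance")
  expect_true(st0$degenerate)
  expect_equal(unname(st0$clr_mean), unname(unclass(same[[1]])))
  expect_equal(unname(st0$clr_sd), rep(0, 12))

  expect_error(fit_standard(specs[1], "X"), "insufficient data")
  expect_error(fit_standard(specs, "X", alpha = 1.2), "alpha")
})

test_that("Monte-Carlo sample recovers a known clr mean", {
  center <- unclass(clr_reference_midpoints("Caeté"))
  center <- center - mean(center)
  set.seed(501)
  m <- matrix(rnorm(10000 * 12, rep(center, each = 10000), 0.15), 10000)
  m <- m - rowMeans(m)
  colnames(m) <- names(center)
  st <- fit_standard(m, "Caeté")
  se <- st$clr_sd / sqrt(10000)
  expect_true(all(abs(st$clr_mean - center) < 3 * se))
  true_cen <- composition_parts(suppressWarnings(clr_back_transform(center)))
  got_cen <- composition_parts(st$centroid)
  expect_true(all(abs(got_cen - true_cen) / true_cen < 0.01))
})

test_that("nutrient indices standardise deviations from the standard", {
  specs <- lapply(1:20, function(s) random_clr(s))
  st <- fit_standard(specs, "X")
  # specimen at the mean -> all zero
  at_mean <- structure(st$clr_mean, class = "clr_vector")
  expect_equal(unname(nutrient_indices(at_mean, st)), rep(0, 12))
  # +1 SD on one part only
  v <- st$clr_mean; v["S"] <- v["S"] + st$clr_sd["S"]
  idx <- nutrient_indices(structure(v, class = "clr_vector"), st)
  expect_equal(unname(idx["S"]), 1)
  expect_equal(unname(idx[names(idx) != "S"]), rep(0, 11))
  # hand-loop oracle on a random specimen
  sp <- random_clr(99)
  idx2 <- nutrient_indices(sp, st)
  brute <- vapply(seq_along(idx2), function(k)
    (unclass(sp)[k] - st$clr_mean[k]) / st$clr_sd[k], numeric(1))
  expect_equal(unname(idx2), unname(brute))
  # zero-SD part is an error naming the part
  st$clr_sd["Mg"] <- 0
  expect_error(nutrient_indices(sp, st), "Mg")
})

test_that("indices are invariant under a measurement-unit change", {
  conc <- random_concentrations(4)
  specs <- lapply(1:20, function(s) random_clr(s))
  st <- fit_standard(specs, "X")
  a <- nutrient_indices(clr_transform(close_composition(conc)), st)
  b <- nutrient_indices(clr_transform(close_composition(conc * 10,
                                                        kappa = 10000)), st)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("nearest neighbours match an exhaustive sort, ties by bank order", {
  bank <- lapply(1:50, function(s) random_clr(s))
  sp <- random_clr(999)
  nn <- nearest_balanced_neighbors(sp, bank, k = 50)
  d <- vapply(bank, clr_distance, numeric(1), b = sp)
  expect_equal(nn$index, order(d))
  expect_equal(nn$epsilon, d[order(d)])
  # specimen in the bank comes first with distance 0
  nn2 <- nearest_balanced_neighbors(bank[[7]], bank, k = 3)
  expect_equal(nn2$index[1], 7)
  expect_equal(nn2$epsilon[1], 0)
  # k beyond bank size returns the whole bank
  expect_equal(nrow(nearest_balanced_neighbors(sp, bank[1:4], k = 10)), 4)
  # exact ties keep bank order
  tie_bank <- list(bank[[2]], bank[[1]], bank[[2]])
  nn3 <- nearest_balanced_neighbors(bank[[2]], tie_bank, k = 3)
  expect_equal(nn3$index, c(1, 3, 2))
  expect_error(nearest_balanced_neighbors(sp, list()), "no-reference")
})
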