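test_that("otsu threshold maximizes between-class variance (smallest tie)", {
  # half zeros, half 255s: every cut separates them; tie-break gives t = 0
  img <- matrix(rep(c(0, 255), each = 50), 10, 10)
  t <- otsu_threshold(img, bit_depth = 8)
  expect_equal(as.numeric(t), 0)
  expect_equal(sum(img > t), 50)

  # 5-level histogram (4,0,0,0,6): exhaustive maximizer agreement
  vals <- rep(c(0, 4), times = c(4, 6))
  t2 <- otsu_threshold(matrix(vals, 2, 5), bit_depth = 8)
  expect_equal(attr(t2, "bin"), oracle_otsu_bin(vals, step = 1))

  # random 8-bit image vs the exhaustive 256-candidate search
  set.seed(1)
  vals3 <- sample(0:255, 400, replace = TRUE)
  t3 <- otsu_threshold(matrix(vals3, 20, 20), bit_depth = 8)
  expect_equal(attr(t3, "bin"), oracle_otsu_bin(vals3, step = 1))

  # 16-bit images use a 256-bin histogram
  set.seed(2)
  vals4 <- sample(0:65535, 900, replace = TRUE)
  t4 <- otsu_threshold(matrix(vals4, 30, 30), bit_depth = 16)
  expect_equal(attr(t4, "bin"), oracle_otsu_bin(vals4, step = 256))
  expect_equal(as.numeric(t4), (attr(t4, "bin") + 1) * 256 - 1)

  expect_error(otsu_threshold(matrix(7, 4, 4)),
               class = "nociquant_otsu_error")
})

test_that("otsu agrees with exhaustive search across many random histograms", {
  set.seed(123)
  for (i in 1:25) {
    n_levels <- sample(2:6, 1)
    levels <- sort(sample(0:255, n_levels))
    counts <- sample(1:20, n_levels, replace = TRUE)
    vals <- rep(levels, counts)
    t <- otsu_threshold(matrix(vals, 1), bit_depth = 8)
    expect_equal(attr(t, "bin"), oracle_otsu_bin(vals, step = 1),
                 info = paste("case", i))
  }
})

test_that("linear enhancement matches the reference upper-decile mean", {
  set.seed(3)
  ref <- matrix(runif(400, 0, 1000), 20, 20)
  same <- match_enhance(ref, upper_decile_mean(ref))
  expect_equal(attr(same, "gain"), 1)
  expect_equal(as.vector(same), as.vector(ref))

  halved <- match_enhance(ref / 2, upper_decile_mean(ref))
  expect_equal(attr(halved, "gain"), 2)

  src <- matrix(runif(400, 0, 300), 20, 20)
  out <- match_enhance(src, upper_decile_mean(ref))
  expect_equal(upper_decile_mean(out), upper_decile_mean(ref),
               tolerance = 1e-6)
  # monotone: pixel ordering unchanged
  expect_identical(order(as.vector(out)), order(as.vector(src)))

  expect_error(match_enhance(matrix(0, 5, 5), 100),
               class = "nociquant_enhance_error")
})

test_that("terminal area normalizes GFP pixels to the mean neuromere size", {
  # counts 100 / 1000 with 10 neuromeres -> normalized area 1.0
  ny <- 40; nx <- 40
  gfp <- matrix(0, ny, nx); gfp[1:10, 1:10] <- 4000      # 100 px
  cd2 <- matrix(0, ny, nx); cd2[1:25, 1:40] <- 4000      # 1000 px
  stk <- image_stack(list(GFP = gfp, CD2 = cd2), bit_depth = 16)
  res <- terminal_area(stk, n_neuromeres = 10)
  expect_equal(res$gfp_pixels, 100L)
  expect_equal(res$cd2_pixels, 1000L)
  expect_equal(res$normalized_area, 1.0)

  # empty clone: an all-zero GFP channel measures zero area
  stk0 <- image_stack(list(GFP = matrix(0, ny, nx), CD2 = cd2),
                      bit_depth = 16)
  res0 <- terminal_area(stk0, n_neuromeres = 10)
  expect_false(res0$excluded)
  expect_equal(res0$normalized_area, 0)

  # constant nonzero channel cannot be binarized -> excluded, not quantified
  stk_const <- image_stack(list(GFP = matrix(100, ny, nx), CD2 = cd2),
                           bit_depth = 16)
  res_c <- terminal_area(stk_const, n_neuromeres = 10)
  expect_true(res_c$excluded)
  expect_match(res_c$exclusion_reason, "Otsu")

  expect_error(terminal_area(image_stack(list(GFP = gfp), bit_depth = 16), 5),
               class = "nociquant_format_error")
})

test_that("normalized area is invariant under integer upsampling", {
  tr <- clone_truth(noise_sd = 0, nz = 1L)
  gen <- generate_clone_image(tr, seed = 1)
  res1 <- terminal_area(gen$stack, tr$n_neuromeres)
  upsample <- function(m, k) m[rep(seq_len(nrow(m)), each = k),
                               rep(seq_len(ncol(m)), each = k)]
  up <- image_stack(list(GFP = upsample(get_channel(max_project(gen$stack),
                                                    "GFP"), 2),
                         CD2 = upsample(get_channel(max_project(gen$stack),
                                                    "CD2"), 2)),
                    bit_depth = 16)
  res2 <- terminal_area(up, tr$n_neuromeres)
  expect_equal(res2$normalized_area, res1$normalized_area)
})

test_that("area recovery stays within 5% relative error at default noise", {
  errs <- vapply(1:100, function(i) {
    tr <- clone_truth()
    gen <- generate_clone_image(tr, seed = 5000 + i)
    res <- terminal_area(gen$stack, tr$n_neuromeres)
    truth_area <- sum(tr$clone_mask) /
      (sum(tr$neuropil_mask) / tr$n_neuromeres)
    abs(res$normalized_area - truth_area) / truth_area
  }, numeric(1))
  expect_lte(mean(errs), 0.05)
})

test_that("profiles align on the entry neuromere", {
  p_mat <- function(idx, tracts, fill) {
    m <- matrix(fill, length(idx), length(tracts),
                dimnames = list(idx, tracts))
    m
  }
  # single clone present only at its entry -> one row, TRUE at offset 0
  p1 <- projection_profile(p_mat(4, c("L", "R"), c(TRUE, FALSE)),
                           entry_index = 4, clone_id = "c1")
  al1 <- align_profiles(list(p1))
  expect_equal(al1$offsets, 0)
  expect_equal(al1$presence[1, "0", ], c(L = TRUE, R = FALSE))

  # translation invariance: same relative shape, different entry segments
  shape <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                  dimnames = list(NULL, c("L", "R")))
  m_a <- shape; rownames(m_a) <- c(3, 4)
  m_b <- shape; rownames(m_b) <- c(5, 6)
  al2 <- align_profiles(list(projection_profile(m_a, 3),
                             projection_profile(m_b, 5)))
  expect_equal(al2$presence[1, , ], al2$presence[2, , ])

  # three hand-written profiles vs hand alignment
  m1 <- matrix(c(TRUE, TRUE), 2, 1, dimnames = list(c(2, 3), "M"))
  m2 <- matrix(c(TRUE, TRUE), 2, 1, dimnames = list(c(4, 5), "M"))
  m3 <- matrix(TRUE, 1, 1, dimnames = list(6, "M"))
  al3 <- align_profiles(list(projection_profile(m1, 2),
                             projection_profile(m2, 5),
                             projection_profile(m3, 6)))
  expect_equal(al3$offsets, c(-1, 0, 1))
  hand <- rbind(c(FALSE, TRUE, TRUE),    # enters at 2, covers 2,3
                c(TRUE, TRUE, FALSE),    # enters at 5, covers 4,5
                c(FALSE, TRUE, FALSE))   # enters at 6, covers 6
  expect_equal(unname(al3$presence[, , "M"]), hand)

  expect_error(projection_profile(
    matrix(FALSE, 1, 1, dimnames = list(1, "M")), 1),
    class = "nociquant_validation_error")
})

test_that("heat-map percentages are clone fractions times 100", {
  m <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
              dimnames = list(c(1, 2), c("L", "R")))
  one <- projection_heatmap(align_profiles(list(projection_profile(m, 1))))
  expect_true(all(one$percent %in% c(0, 100)))
  expect_equal(one$n_clones, 1L)

  # 4 clones, 3 present at offset +1
  mk <- function(rows, idx, entry) {
    mm <- matrix(rows, length(idx), 1, dimnames = list(idx, "M"))
    projection_profile(mm, entry)
  }
  clones <- list(mk(c(TRUE, TRUE), c(1, 2), 1),
                 mk(c(TRUE, TRUE), c(3, 4), 3),
                 mk(c(TRUE, TRUE), c(2, 3), 2),
                 mk(TRUE, 5, 5))
  hm <- projection_heatmap(align_profiles(clones))
  expect_equal(hm$percent["1", "M"], 75)
  expect_equal(hm$percent["0", "M"], 100)

  # random 20-clone set vs a brute-force count oracle
  set.seed(9)
  tracts <- c("L", "M", "R")
  profs <- lapply(1:20, function(i) {
    entry <- sample(1:5, 1)
    span <- sample(1:3, 1)
    idx <- entry:(entry + span - 1)
    pres <- matrix(runif(span * 3) < 0.5, span, 3,
                   dimnames = list(idx, tracts))
    pres[1, sample(3, 1)] <- TRUE  # guarantee entry presence
    projection_profile(pres, entry)
  })
  al <- align_profiles(profs)
  hm2 <- projection_heatmap(al)
  expect_true(all(hm2$percent >= 0 & hm2$percent <= 100))
  for (o in as.character(al$offsets)) {
    for (tr in tracts) {
      cnt <- 0L
      for (i in seq_along(profs)) {
        p <- profs[[i]]
        row <- as.character(as.integer(o) + p$entry_index)
        if (row %in% rownames(p$presence) && p$presence[row, tr]) {
          cnt <- cnt + 1L
        }
      }
      expect_equal(hm2$percent[o, tr], 100 * cnt / 20)
    }
  }
})
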