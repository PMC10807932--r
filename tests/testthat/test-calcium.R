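test_that("patient threshold implements mean + k*SD of aortic attenuation", {
  arr <- array(0, c(6, 6, 6))
  ao <- array(0, c(6, 6, 6))
  ao[2:5, 2:5, 2:5] <- 1
  img <- image_volume(arr + 450)
  expect_equal(patient_threshold(img, label_map(ao)), 450)  # sigma = 0

  set.seed(4)
  vals <- 450 + 20 * as.numeric(scale(rnorm(64)))  # mean 450, sample SD 20
  arr2 <- array(0, c(6, 6, 6))
  arr2[ao == 1] <- vals
  img2 <- image_volume(arr2)
  expect_equal(patient_threshold(img2, label_map(ao), 2.5), 500,
               tolerance = 1e-9)
  expect_equal(patient_threshold(img2, label_map(ao), 0), 450,
               tolerance = 1e-9)
  expect_error(patient_threshold(img, label_map(array(0, c(6, 6, 6)))),
               "empty")
})

test_that("candidate detection thresholds inside the dilated lumen", {
  ph <- ph_lesion()
  theta <- patient_threshold(ph$image, ph$aorta)
  cand <- detect_candidates(ph$image, ph$coronary, theta)
  expect_equal(cand$n, 2)  # two separated lesions, two components
  # nothing above an impossible threshold
  none <- detect_candidates(ph$image, ph$coronary, 1e5)
  expect_equal(none$n, 0)
  # search volume contains and exceeds the lumen
  expect_true(all(cand$search[ph$coronary$data > 0]))
  expect_gt(sum(cand$search), sum(ph$coronary$data))
})

test_that("region growing reaches the same fixpoint as brute-force closure", {
  set.seed(9)
  img <- array(runif(10^3, 0, 100), c(10, 10, 10))
  seeds <- array(0L, c(10, 10, 10))
  seeds[5, 5, 5] <- 1L
  allowed <- array(1L, c(10, 10, 10))
  thr <- 40
  fast <- array(corochar:::.grow_cpp(as.numeric(img), seeds, allowed,
                                     dim(img), thr), dim(img))
  slow <- brute_grow(img, seeds, allowed, thr)
  expect_identical(fast == 1, slow)
  expect_true(all(fast[seeds == 1] == 1))  # output contains the input
})

test_that("growing is monotone in the threshold and never shrinks candidates", {
  ph <- ph_lesion()
  theta <- patient_threshold(ph$image, ph$aorta)
  cand_lo <- detect_candidates(ph$image, ph$coronary, theta - 40)
  cand_hi <- detect_candidates(ph$image, ph$coronary, theta)
  expect_true(all(which(cand_hi$labels > 0) %in% which(cand_lo$labels > 0)))
  grown <- grow_lesions(ph$image, cand_hi, ph$coronary)
  expect_true(all(which(cand_hi$labels > 0) %in% which(grown$labels > 0)))
})

test_that("artifact filter removes sub-millimetric lesions by axial area", {
  labs <- array(0L, c(12, 12, 6))
  labs[2, 2, 2] <- 1L                     # single voxel: 0.16 mm^2
  labs[6:8, 6:8, 3] <- 2L                 # 3x3 in-plane: 1.44 mm^2
  lesions <- list(labels = labs, n = 2)
  out <- filter_artifacts(lesions, spacing = c(0.4, 0.4, 0.4))
  expect_equal(out$n, 1)
  expect_equal(sort(unique(as.vector(out$labels))), c(0L, 1L))
  expect_equal(sum(out$labels == 1), 9)
  # volume mode: the 9-voxel blob is 0.576 mm^3 and gets removed too
  out2 <- filter_artifacts(lesions, spacing = c(0.4, 0.4, 0.4),
                           area_mode = "volume")
  expect_equal(out2$n, 0)
  empty <- filter_artifacts(list(labels = array(0L, c(4, 4, 4)), n = 0),
                            spacing = c(0.4, 0.4, 0.4))
  expect_equal(empty$n, 0)
})

test_that("centerline projection yields abscissa, extent and zone per lesion", {
  tree <- synthetic_tree(60)
  vol <- image_volume(array(100, c(40, 8, 8)), spacing = c(1, 1, 1),
                      origin = c(0, -3.5, -3.5))
  labs <- array(0L, dim(vol$data))
  labs[22:26, 4, 4] <- 1L   # 5 voxels along x at world x = 21..25
  les <- project_to_centerline(list(labels = labs), tree, vol)
  expect_equal(les$min_abscissa_mm, 21)
  expect_equal(les$max_abscissa_mm, 25)
  expect_equal(les$extent_mm, 4)
  expect_equal(les$zone, "medial")  # g of min-abscissa point = 0.35
  labs2 <- array(0L, dim(vol$data))
  labs2[13, 4, 4] <- 1L     # world x = 12, g = 0.2: proximal, extent 0
  les2 <- project_to_centerline(list(labels = labs2), tree, vol)
  expect_equal(les2$zone, "proximal")
  expect_equal(les2$extent_mm, 0)
})

test_that("volume score, PPV and distances aggregate consistently", {
  tab <- data.frame(lesion = 1:2, n_voxels = c(10, 20),
                    volume_mm3 = c(30, 20), mean_hu = c(700, 650),
                    min_abscissa_mm = c(5, 40), max_abscissa_mm = c(8, 45),
                    extent_mm = c(3, 5), zone = c("proximal", "medial"),
                    branch = c(1L, 1L))
  rep <- calcium_score(tab, vessel_volume_mm3 = 2000)
  expect_equal(rep$vs_total, 50)
  expect_equal(sum(rep$vs_zone), rep$vs_total)
  expect_equal(rep$ppv, 2.5)
  expect_equal(rep$shortest_distance_mm, 5)
  expect_equal(rep$longest_distance_mm, 40)
  expect_error(calcium_score(tab, 0), "positive")
  empty <- calcium_score(tab[0, ], 2000)
  expect_equal(empty$vs_total, 0)
  expect_equal(empty$ppv, 0)
})

test_that("end-to-end calcium analysis recovers phantom lesions", {
  ph <- ph_lesion()
  rep <- analyze_calcium(ph$image, ph$coronary, ph$aorta, tree_lesion())
  truth <- ph$truth$lesions
  expect_equal(nrow(rep$lesions), nrow(truth))
  ord <- order(rep$lesions$min_abscissa_mm)
  expect_lt(max(abs(rep$lesions$extent_mm[ord] - truth$extent_mm)), 1.5)
  expect_lt(max(abs(rep$lesions$min_abscissa_mm[ord] -
                      truth$min_abscissa_mm)), 1.5)
  expect_true(all(abs(rep$lesions$volume_mm3[ord] / truth$volume_mm3 - 1)
                  < 0.45))
  expect_gt(rep$growth_threshold, patient_threshold(ph$image, ph$aorta) - 100)
  # determinism
  rep2 <- analyze_calcium(ph$image, ph$coronary, ph$aorta, tree_lesion())
  expect_identical(rep$lesions, rep2$lesions)
})
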