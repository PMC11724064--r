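brute_pearson <- function(x, y) {
  # two-pass product-moment formula, written independently of pearson_r()
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

test_that("pearson_r matches the brute-force product-moment formula", {
  x <- c(10, 20, 30, 40)
  y <- c(12, 18, 33, 41)
  expect_equal(pearson_r(x, y)$r, brute_pearson(x, y), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    x <- runif(n, 0, 100)
    y <- runif(n, 0, 100)
    res <- pearson_r(x, y)
    expect_equal(res$r, brute_pearson(x, y), tolerance = 1e-10)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
    expect_equal(res$n, n)
    # invariance under positive affine maps
    expect_equal(pearson_r(2.5 * x + 7, y)$r, res$r, tolerance = 1e-10)
  }
})

test_that("pearson_r handles perfect and degenerate relationships", {
  x <- c(10, 30, 50, 70)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x + 100)$r, -1)
  expect_error(pearson_r(x, rep(5, 4)), class = "leafhair_undefined_correlation")
  expect_error(pearson_r(c(1, 2), c(3, 4)))
  expect_error(pearson_r(x, x[1:3]))
})

test_that("rmse follows its closed form and basic inequalities", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(10, 13), 3)
  expect_error(rmse(1:3, 1:4))
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    x <- runif(n, 0, 100)
    y <- runif(n, 0, 100)
    expect_equal(rmse(x, y), rmse(y, x))
    expect_equal(rmse(x, y), sqrt(mean((x - y)^2)), tolerance = 1e-12)
    expect_gte(rmse(x, y) + 1e-12, abs(mean(signed_error(x, y))))
  }
})

test_that("signed error keeps the direction of the bias", {
  expect_equal(signed_error(80, 50), 30)
  expect_equal(signed_error(30, 50), -20)
  expect_equal(signed_error(64, 64), 0)
})

test_that("panel comparison computes per-evaluator agreement against the reference", {
  imgs <- sprintf("img%d", 1:6)
  records <- dplyr::bind_rows(
    tibble::tibble(
      evaluator_id = "model", evaluator_class = "model", image_id = imgs,
      method = "slice_classification", value = c(0, 15, 35, 55, 75, 95)
    ),
    tidyr::expand_grid(
      evaluator_id = c("expert1", "expert2"),
      method = c("slice_classification", "manual_rating"),
      image_id = imgs
    )
  )
  ref_vals <- c(0, 15, 35, 55, 75, 95)
  names(ref_vals) <- imgs
  records$value[is.na(records$value)] <- 0
  records <- dplyr::mutate(records,
    evaluator_class = ifelse(evaluator_id == "model", "model", "expert"),
    value = ifelse(evaluator_id == "model", value,
      ifelse(evaluator_id == "expert1", ref_vals[image_id],
        pmin(100, ref_vals[image_id] + 5)
      )
    )
  )
  panels <- compare_panels(records, reference_id = "model")
  s <- panels$summaries
  expect_equal(nrow(s), 4L) # 2 evaluators x 2 methods
  expect_equal(nrow(panels$errors), 24L) # 2 x 2 x 6 error rows

  e1 <- dplyr::filter(s, evaluator_id == "expert1")
  expect_true(all(e1$rmse == 0))
  expect_equal(e1$r, rep(1, nrow(e1)), tolerance = 1e-12)
  e1err <- dplyr::filter(panels$errors, evaluator_id == "expert1")
  expect_true(all(e1err$error == 0))

  # a constant +5 shift keeps R at 1 but moves rmse and signed error to 5
  e2 <- dplyr::filter(s, evaluator_id == "expert2")
  expect_true(all(abs(e2$r - 1) < 1e-12))
  expect_true(all(e2$rmse == 5))
  expect_true(all(dplyr::filter(panels$errors, evaluator_id == "expert2")$error == 5))
})

test_that("images without a reference value are excluded with a warning", {
  records <- tibble::tibble(
    evaluator_id = c("model", "model", "e1", "e1", "e1"),
    evaluator_class = c("model", "model", "expert", "expert", "expert"),
    image_id = c("a", "b", "a", "b", "c"),
    method = "manual_rating",
    value = c(10, 20, 12, 18, 50)
  )
  expect_warning(panels <- compare_panels(records, "model"), "without a reference")
  expect_equal(sort(unique(panels$errors$image_id)), c("a", "b"))
  expect_error(compare_panels(records, "absent"))
})

test_that("ratings tables round-trip through CSV with validation", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ratings.csv")
  r <- tibble::tibble(
    evaluator_id = c("model", "e1"), evaluator_class = c("model", "novice"),
    image_id = "img1", method = "manual_rating", value = c(40, 60)
  )
  readr::write_csv(r, path)
  rr <- read_ratings(path)
  expect_equal(nrow(rr), 2L)
  bad <- r
  bad$value[1] <- 140
  readr::write_csv(bad, path)
  expect_error(read_ratings(path), "0, 100")
  dup <- dplyr::bind_rows(r, r[1, ])
  readr::write_csv(dup, path)
  expect_error(read_ratings(path), "duplicate")
})

test_that("panel outputs export as tidy CSVs and plot", {
  records <- tibble::tibble(
    evaluator_id = rep(c("model", "e1"), each = 4),
    evaluator_class = rep(c("model", "novice"), each = 4),
    image_id = rep(sprintf("i%d", 1:4), 2),
    method = "manual_rating",
    value = c(10, 30, 50, 70, 20, 35, 45, 80)
  )
  panels <- compare_panels(records, "model")
  dir <- withr::local_tempdir()
  paths <- write_panel_csvs(panels, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["errors"]], show_col_types = FALSE)
  expect_equal(nrow(back), 4L)
  expect_s3_class(autoplot(panels), "ggplot")
  expect_identical(tidy(panels), panels$errors)
  expect_identical(glance(panels), panels$summaries)
})
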