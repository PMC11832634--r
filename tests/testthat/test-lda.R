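# hand-built 1-D two-class model on the standardised scale
toy_model <- function(m = 1, priors = c(a = 0.5, b = 0.5)) {
  structure(list(classes = c("a", "b"),
                 means = matrix(c(-m, m), 2, 1,
                                dimnames = list(c("a", "b"), "CA")),
                 pooled_cov = matrix(1, 1, 1),
                 precision = matrix(1, 1, 1),
                 priors = priors,
                 center = c(CA = 0), scale = c(CA = 1),
                 lambda = 0, min_class_size = 0L,
                 n_per_class = c(1L, 1L), features = "CA",
                 excluded = character(0), x = NULL, y = NULL,
                 call = NULL),
            class = "tclda")
}

test_that("symmetric two-class posteriors follow the logistic closed form", {
  m <- toy_model()
  expect_equal(unname(predict(m, matrix(0))[1, ]), c(0.5, 0.5))
  p1 <- predict(m, matrix(1))[1, ]
  expect_equal(unname(p1["b"]), 1 / (1 + exp(-2)), tolerance = 1e-12)
})

test_that("degenerate within-class scatter errors at lambda 0, fits above", {
  d <- data.frame(res_type = c("A", "A", "S", "S"),
                  CA = c(0, 0, 2, 2))
  expect_error(tclda(d, features = "CA", lambda = 0, min_class_size = 2),
               "singular|lambda")
  m <- tclda(d, features = "CA", lambda = 0.1, min_class_size = 2)
  expect_s3_class(m, "tclda")
  p <- predict(m, data.frame(CA = 2))
  expect_gt(p[1, "S"], 0.99)
})

test_that("prior modes behave as documented", {
  set.seed(5)
  d <- random_training(3, 2, 10)
  m_unif <- tclda(d, features = names(d)[-1], lambda = 0.05,
                  priors = "uniform")
  expect_equal(unname(m_unif$priors), rep(1 / 3, 3))
  # sequence priors: counts of model classes in the sequence, renormalised
  seqn <- c(rep(m_unif$classes[1], 4), rep(m_unif$classes[2], 2),
            rep(m_unif$classes[3], 2), "P", "G")
  m_seq <- tclda(d, features = names(d)[-1], lambda = 0.05,
                 priors = "sequence", sequence = seqn)
  expect_equal(unname(m_seq$priors), c(0.5, 0.25, 0.25))
  # posterior for a class is nondecreasing in its prior
  x <- d[1, , drop = FALSE]
  for (w in c(1, 2, 5, 10)) {
    pr <- setNames(c(w, 1, 1), m_unif$classes)
    mw <- tclda(d, features = names(d)[-1], lambda = 0.05, priors = pr)
    if (w > 1) expect_gte(predict(mw, x)[1, m_unif$classes[1]],
                          p_prev[1, m_unif$classes[1]])
    p_prev <- predict(mw, x)
  }
})

test_that("posteriors equal the Gaussian-density Bayes oracle", {
  set.seed(6)
  for (trial in 1:25) {
    K <- sample(2:8, 1)
    d <- sample(1:6, 1)
    train <- random_training(K, d, sample(4:9, 1))
    lam <- sample(c(0, 0.05, 0.3), 1)
    m <- tclda(train, features = names(train)[-1], lambda = lam,
               priors = "uniform")
    q <- random_training(K, d, 2)
    got <- predict(m, q)
    want <- oracle_posterior(m, q)
    expect_equal(got, want, tolerance = 1e-8)
    expect_equal(unname(rowSums(got)), rep(1, nrow(got)), tolerance = 1e-9)
  }
})

test_that("posteriors are invariant to positive feature rescaling at lambda 0", {
  set.seed(7)
  train <- random_training(4, 3, 8)
  q <- random_training(4, 3, 2)
  feats <- names(train)[-1]
  m0 <- tclda(train, features = feats, lambda = 0)
  train2 <- train; q2 <- q
  train2[[feats[2]]] <- train2[[feats[2]]] * 37
  q2[[feats[2]]] <- q2[[feats[2]]] * 37
  m1 <- tclda(train2, features = feats, lambda = 0)
  expect_equal(predict(m0, q), predict(m1, q2), tolerance = 1e-8)
})

test_that("statistics-based training reproduces closed-form separations", {
  tab <- data.frame(type = c("A", "S"), feature = "CA",
                    mean = c(52, 54), sd = 0.5)
  m <- tclda_from_statistics(type_statistics(tab), features = "CA")
  # means 4 sd apart: a point at either mean is classified near-certainly;
  # closed form: logistic of half the squared Mahalanobis separation
  p <- predict(m, data.frame(CA = 52))[1, "A"]
  expect_equal(unname(p), 1 / (1 + exp(-8)), tolerance = 1e-10)
  # equal means: posteriors equal priors for any x
  tab2 <- data.frame(type = c("A", "S", "T"), feature = "CA",
                     mean = 52, sd = 0.5)
  m2 <- tclda_from_statistics(type_statistics(tab2), features = "CA",
                              priors = setNames(c(0.6, 0.3, 0.1),
                                                c("A", "S", "T")))
  expect_equal(unname(predict(m2, data.frame(CA = 40))[1, ]),
               c(0.6, 0.3, 0.1))
  # classes missing a feature cell are dropped with a warning
  tab3 <- rbind(tab, data.frame(type = "T", feature = "CB",
                                mean = 70, sd = 0.5))
  expect_warning(m3 <- tclda_from_statistics(type_statistics(tab3),
                                             features = "CA"), "dropped")
  expect_setequal(m3$classes, c("A", "S"))
  # a subset requiring TCs fails when the table has none
  expect_error(suppressWarnings(
    tclda_from_statistics(type_statistics(tab), features = subset_preset("v"))),
    "classes")
})

test_that("class exclusion removes types and renormalises priors", {
  st <- default_statistics()
  expect_warning(m <- tclda_from_statistics(st, features = c("HN", "N", "CA")),
                 "dropped")
  expect_equal(length(m$classes), 19)  # proline has no HN statistics
  m18 <- exclude_classes(m, c("G", "P"))
  expect_equal(length(m18$classes), 18)
  expect_equal(sum(m18$priors), 1)
  expect_identical(exclude_classes(m18, character(0)), m18)
  expect_error(exclude_classes(m18, setdiff(m18$classes, "A")), "2 classes")
})

test_that("the subset family refits for each missingness pattern", {
  set.seed(8)
  cfg <- generator_config(length = 400, seed = 8)
  bm <- make_benchmark(cfg, 0.7, 0.3)
  feats <- subset_preset("v")
  fam <- tclda_family(bm$train, feats, exclude = "G",
                      min_class_size = 2)
  full <- tclda(bm$train, feats, exclude = "G", min_class_size = 2,
                keep_data = FALSE)
  q <- bm$query[1:6, ]
  # complete queries: identical to the full-model posterior
  post_fam <- predict(fam, q)
  expect_equal(matrix(post_fam[, full$classes], nrow(q)),
               unname(predict(full, q)), tolerance = 1e-12)
  expect_true(all(vapply(attr(post_fam, "subset"), identical,
                         logical(1), feats)))
  # a query missing CB uses the CB-free refit
  q_nocb <- q
  q_nocb$CB <- NA_real_
  q_nocb$TC1_CB <- NA_real_
  post2 <- predict(fam, q_nocb)
  expect_true(all(vapply(attr(post2, "subset"), function(s)
    !any(c("CB", "TC1_CB") %in% s), logical(1))))
  expect_equal(unname(rowSums(post2)), rep(1, nrow(q_nocb)),
               tolerance = 1e-9)
  # identical missingness -> one cached fit (plus the full-subset fit)
  expect_equal(length(ls(fam$cache)), 2)
  # a nearly empty spin system still classifies, flagged low-information
  q_hn <- q[1, ]
  q_hn[setdiff(names(q_hn), c("id", "res_type", "res_num", "HN"))] <- NA
  post3 <- predict(fam, q_hn)
  expect_equal(attr(post3, "n_features"), 1L)
  expect_equal(sum(post3), 1, tolerance = 1e-9)
})
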