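test_that("MSE loss matches hand arithmetic and is quadratic", {
  expect_equal(mse_loss(c(1, 3), c(1, 3)), 0)
  expect_equal(mse_loss(c(1, 3), c(2, 5)), 2.5)
  y <- rnorm(10); r <- rnorm(10)
  expect_equal(mse_loss(y, y + 3 * r), 9 * mse_loss(y, y + r))
  expect_error(mse_loss(1:3, 1:2), "length")
})

test_that("metric identities hold on random prediction vectors", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    y <- rnorm(n, 70, 10); p <- rnorm(n, 70, 10)
    m <- regression_metrics(y, p)
    expect_equal(m[["RMSE"]]^2, m[["MSE"]], tolerance = 1e-9)
    expect_lte(m[["MAE"]], m[["RMSE"]] + 1e-12)
    expect_true(all(m >= 0))
  }
})

test_that("training descends, is seed-deterministic, and freezes at lr 0", {
  co <- small_sim_cohort(30, seed = 51)
  mc <- model_config(k = 100, seed = 2)    # k large: sampling is a no-op
  tc <- train_config(epochs = 8, seed = 3)
  fit1 <- train(co, model_config = mc, tc = tc)
  fit2 <- train(co, model_config = mc, tc = tc)
  expect_identical(fit1$params, fit2$params)
  expect_lt(tail(fit1$loss_trace, 1), fit1$loss_trace[1])

  tc0 <- train_config(epochs = 5, learning_rate = 0, seed = 3)
  fit0 <- train(co, model_config = mc, tc = tc0)
  expect_identical(fit0$params, init_graphformer(mc))
  expect_equal(diff(range(fit0$loss_trace)), 0, tolerance = 1e-12)
})

test_that("cross-validation folds partition the cohort", {
  co <- small_sim_cohort(10, seed = 52)
  fm <- cross_validate(co, tc = train_config(folds = 2, epochs = 1, seed = 4),
                       predictor = "mean")
  folds <- attr(fm, "folds")
  expect_equal(sort(unname(lengths(folds))), c(5, 5))
  expect_setequal(unlist(folds), names(co$patients))
  expect_equal(anyDuplicated(unlist(folds)), 0)
  expect_error(cross_validate(subset_cohort(co, 1:3),
                              tc = train_config(folds = 10)),
               "fewer patients")
})

test_that("the mean predictor's error approaches the target spread", {
  co <- small_sim_cohort(200, seed = 53)
  fm <- cross_validate(co, tc = train_config(folds = 5, seed = 5),
                       predictor = "mean")
  preds <- attr(fm, "predictions")
  expect_equal(summary(fm)$mean[["RMSE"]], sd(preds$target), tolerance = 0.1)
})

test_that("multistep evaluation excludes shallow patients per step", {
  co <- small_sim_cohort(40, seed = 54)
  fit <- train(co, model_config = model_config(seed = 2),
               tc = train_config(epochs = 2, seed = 6))
  ms <- evaluate_multistep(co, fit, steps = c(1, 2))
  expect_equal(ms$horizon, c(1, 2))
  # DBP is always measured, so depth alone decides inclusion per step
  n3 <- sum(vapply(co$patients, function(p) length(p$visits) >= 3, TRUE))
  expect_equal(ms$n[2], n3)
  expect_equal(ms$n[1], n_patients(co))
  expect_equal(ms$n_excluded, c(0, n_patients(co) - n3))
  # a 2-visit patient is forecastable at horizon 1 only
  p2 <- toy_patient("two", list(c(DBP = 70, SBP = 120), c(DBP = 72)))
  expect_false(is_skipped(build_patient_graph(p2, "Lab", horizon = 1)))
  expect_true(is_skipped(build_patient_graph(p2, "Lab", horizon = 2)))
})

test_that("stratification reproduces the named medication subgroups", {
  mkp <- function(id, drugs, subtype = NA_character_) {
    p <- toy_patient(id, list(c(DBP = 70), c(DBP = 72)), subtype = subtype)
    p$drugs <- drugs
    suppressWarnings(assign_drug_category(p))
  }
  co <- cohort(list(
    mkp("a", c("Losartan", "Valsartan"), "HFpEF"),
    mkp("b", c("Metoprolol", "Furosemide"), "HFrEF"),
    mkp("c", c("Metoprolol", "Metformin"), "HFpEF"),
    mkp("d", "Metoprolol")))

  intra <- stratify(co, "intra_combo")
  expect_true("ARB:Losartan+Valsartan" %in% names(intra))
  expect_identical(names(intra$`ARB:Losartan+Valsartan`$patients), "a")

  inter <- stratify(co, "inter_combo")
  expect_true("BB:Metoprolol x LD:Furosemide" %in% names(inter))

  poly <- stratify(co, "polypharmacy")
  expect_true("Metoprolol + Metformin" %in% names(poly))

  cats <- stratify(co, "category")
  expect_setequal(names(cats$BB$patients), c("b", "c", "d"))
  expect_true("a" %in% names(cats$ARB$patients))

  top <- stratify(co, "top_drug")
  expect_true("BB:Metoprolol" %in% names(top))

  sub <- stratify(co, "subtype")
  expect_setequal(names(sub$HFpEF$patients), c("a", "c"))
  expect_identical(names(sub$HFrEF$patients), "b")
  expect_identical(unname(attr(sub, "counts")), c(2L, 1L))

  expect_error(stratify(co, "nonsense"))
})

test_that("embedding export is one row per patient with a silhouette score", {
  co <- small_sim_cohort(30, seed = 55)
  fit <- train(co, model_config = model_config(seed = 2),
               tc = train_config(epochs = 2, seed = 7))
  emb <- export_embeddings(co, fit)
  preds <- predict_cohort(fit, co)
  expect_equal(nrow(emb), nrow(preds))
  expect_true(is.numeric(attr(emb, "silhouette")))

  # single-subtype cohort: silhouette is not applicable
  one <- co
  for (i in seq_along(one$patients)) one$patients[[i]]$subtype <- "HFrEF"
  emb1 <- export_embeddings(one, fit)
  expect_true(is.na(attr(emb1, "silhouette")))
})

test_that("the MLP baseline shares the protocol and respects zero epochs", {
  co <- small_sim_cohort(40, seed = 56)
  tc <- train_config(epochs = 2, folds = 2, seed = 8)
  fm <- mlp_baseline(co, tc)
  expect_s3_class(fm, "fold_metrics")
  expect_equal(nrow(fm), 2)
  expect_true(all(fm$RMSE > 0))

  # zero-epoch training equals the random-init predictor
  scaler <- fit_value_scaler(co)
  des <- graphDBP:::mlp_design(co, 3, 1, scaler)
  tc0 <- train_config(epochs = 0, seed = 8)
  m0 <- graphDBP:::mlp_train(des$X, des$y, tc0, 16)
  init <- graphDBP:::mlp_init(ncol(des$X), 16, tc0$seed)
  expect_identical(m0$params, init)
})

test_that("checkpoints reload to an equivalent model", {
  co <- small_sim_cohort(25, seed = 57)
  fit <- train(co, model_config = model_config(seed = 2),
               tc = train_config(epochs = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  p1 <- predict_cohort(fit, co)
  p2 <- predict_cohort(back, co)
  expect_equal(p2$prediction, p1$prediction, tolerance = 1e-8)
  expect_error(load_checkpoint(file.path(tempdir(), "nope.json")), "no such")
})

test_that("held-out-only co-occurrence never unmasks training attention", {
  # the pair (SVR, cancer) co-occurs only in the held-out patient
  train_pats <- lapply(1:6, function(i)
    toy_patient(paste0("tr", i), list(c(DBP = 70 + i, SBP = 120),
                                      c(DBP = 72 + i, SBP = 122),
                                      c(DBP = 74 + i))))
  held <- toy_patient("held", list(c(DBP = 70, SVR = 1100, cancer = 1),
                                   c(DBP = 72, SVR = 1101, cancer = 1),
                                   c(DBP = 74)))
  vocab <- c("DBP", "SBP", "SVR", "cancer")
  train_co <- cohort(train_pats, vocabulary = vocab)
  mask <- build_cooccurrence_mask(train_co)
  expect_equal(mask$M["SVR", "cancer"], 0)

  g <- build_patient_graph(held, "ALL", horizon = 1)
  nm <- expand_mask_to_nodes(mask, g)
  params <- random_attention_params(1, 2, with_proj = FALSE)
  W <- attr(masked_attention(g$X, params, nm), "weights")[[1]]
  svr <- grep("^SVR", rownames(g$A))
  can <- grep("^cancer", rownames(g$A))
  expect_true(all(W[svr, can] == 0))
  expect_true(all(W[can, svr] == 0))
})
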