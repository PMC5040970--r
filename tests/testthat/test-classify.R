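mk_subs <- function(descs) {
  submission_set(sprintf("S%02d", seq_along(descs)),
                 rep("GEO", length(descs)), descs,
                 as.list(paste0("a", seq_along(descs))))
}

test_that("keyword assignment is multi-label, case-insensitive and plural-aware", {
  subs <- mk_subs(c("Root tissue under salt STRESS",
                    "",
                    "profiling of seedlings at dawn"))
  cfg <- keyword_config()
  out <- keyword_assign(subs, cfg)
  s1 <- out$class_name[out$submission_id == "S01"]
  expect_setequal(s1, c("Root", "Stress"))
  expect_equal(out$class_name[out$submission_id == "S03"], "Seedling")
  expect_equal(attr(out, "unassigned"), "S02")
  # deterministic
  out2 <- keyword_assign(subs, cfg)
  expect_equal(out, out2, ignore_attr = TRUE)
})

test_that("phrases match as token sequences", {
  subs <- mk_subs(c("whole plant extracts after cold treatment",
                    "the plant was whole"))
  out <- keyword_assign(subs, keyword_config())
  expect_true("Whole Plant" %in%
                out$class_name[out$submission_id == "S01"])
  expect_false("Whole Plant" %in%
                 out$class_name[out$submission_id == "S02"])
})

test_that("overrides apply last-wins with an audit trail", {
  subs <- mk_subs(c("root under stress"))
  asg <- keyword_assign(subs, keyword_config())

  rm1 <- tibble::tibble(submission_id = "S01", action = "remove",
                        basis = "process", class_name = "Stress")
  out <- apply_overrides(asg, rm1)
  expect_false("Stress" %in% out$class_name)
  expect_true("Root" %in% out$class_name)

  addrm <- tibble::tibble(submission_id = c("S01", "S01"),
                          action = c("add", "remove"),
                          basis = "tissue", class_name = "Leaf")
  out2 <- apply_overrides(asg, addrm)
  expect_false("Leaf" %in% out2$class_name)
  expect_equal(nrow(attr(out2, "audit")), 2L)

  empty <- tibble::tibble(submission_id = character(), action = character(),
                          basis = character(), class_name = character())
  expect_equal(apply_overrides(asg, empty)[, 1:3], asg[, 1:3])

  bad <- tibble::tibble(submission_id = "S99", action = "remove",
                        basis = "tissue", class_name = "Root")
  expect_error(apply_overrides(asg, bad), class = "validation_error")
})

test_that("partitioning gives each class exactly its submissions' columns", {
  m <- random_expr(4, 6)
  colnames2 <- paste0("a", 1:6)
  subs <- submission_set(c("S1", "S2", "S3"), rep("GEO", 3),
                         c("root and leaf tissue", "leaf samples",
                           "unrelated words"),
                         list(c("a1", "a2"), c("a3", "a4"), c("a5", "a6")))
  asg <- keyword_assign(subs, keyword_config())
  parts <- partition_matrices(m, asg, subs)
  expect_setequal(colnames(parts[["tissue/Root"]]), c("a1", "a2"))
  expect_setequal(colnames(parts[["tissue/Leaf"]]),
                  c("a1", "a2", "a3", "a4"))  # S1 is in both classes
  # union of class columns plus unassigned covers all columns
  covered <- unique(unlist(lapply(parts, colnames)))
  unassigned_cols <- unlist(subs$array_ids[subs$submission_id %in%
                                             attr(asg, "unassigned")])
  expect_setequal(c(covered, unassigned_cols), colnames(m))
})

test_that("classes with no surviving arrays are dropped with a warning", {
  m <- random_expr(4, 2)
  subs <- submission_set(c("S1", "S2"), c("GEO", "GEO"),
                         c("root tissue", "flower buds"),
                         list(c("a1", "a2"), c("zz1", "zz2")))
  asg <- keyword_assign(subs, keyword_config())
  expect_warning(parts <- partition_matrices(m, asg, subs),
                 regexp = "Flower")
  expect_named(parts, "tissue/Root")
})

test_that("classification summaries count experiments and arrays", {
  subs <- submission_set(c("S1", "S2"), c("GEO", "GEO"),
                         c("root tissue", "root hairs under stress"),
                         list(c("a1", "a2", "a3"), "a4"))
  asg <- keyword_assign(subs, keyword_config())
  s <- classification_summary(asg, subs)
  root <- s[s$class_name == "Root", ]
  expect_equal(root$n_experiments, 2L)
  expect_equal(root$n_arrays, 4L)
})

test_that("keyword configuration round-trips through YAML", {
  cfg <- keyword_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_keyword_config(cfg, path)
  back <- read_keyword_config(path)
  expect_setequal(paste(back$basis, back$class_name),
                  paste(cfg$basis, cfg$class_name))
  i <- which(back$basis == "tissue" & back$class_name == "Root")
  j <- which(cfg$basis == "tissue" & cfg$class_name == "Root")
  expect_setequal(back$keywords[[i]], cfg$keywords[[j]])
  expect_error(keyword_config(list(tissue = list(Root = character()))),
               class = "validation_error")
})
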