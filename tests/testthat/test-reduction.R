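test_that("there are 12 edge transforms in 6 boundary pairs related by reflections", {
  ets <- s6_edge_transforms()
  expect_length(ets, 12)
  expect_identical(vapply(ets, `[[`, integer(1), "boundary") %in% 1:6, rep(TRUE, 12))
  expect_length(unique(vapply(ets, function(e) paste(e$matrix, collapse = ""), character(1))), 12)
  refl_keys <- vapply(s6_reflections(), function(o) paste(o$matrix, collapse = ""), character(1))
  for (b in 1:6) {
    m1 <- sellingr:::edge_transform(b, 1)$matrix
    m2 <- sellingr:::edge_transform(b, 2)$matrix
    # variant 2 = (some reflection) %*% variant 1
    rel <- m2 %*% solve(m1)
    expect_true(paste(round(rel), collapse = "") %in% refl_keys)
  }
})

test_that("each reduction matrix is a lattice-preserving involution; its boundary form is orthogonal", {
  for (e in s6_edge_transforms()) {
    expect_equal(e$matrix %*% e$matrix, diag(6), ignore_attr = TRUE)
    expect_equal(t(e$vcp_matrix) %*% e$vcp_matrix, diag(6), ignore_attr = TRUE)
    # the two forms agree on the boundary hyperplane s_b = 0
    withr::with_seed(e$boundary, {
      x <- rnorm(6); x[e$boundary] <- 0
      expect_equal(as.numeric(e$matrix %*% x), as.numeric(e$vcp_matrix %*% x),
                   tolerance = 1e-14)
      # and the boundary action preserves the norm
      expect_equal(sum((e$matrix %*% x)^2), sum(x^2), tolerance = 1e-12)
    })
  }
})

test_that("applying an edge transform twice to a boundary point returns the same lattice", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      s <- -runif(6, 0, 5)
      b <- sample.int(6, 1)
      s[b] <- 0
      e <- sellingr:::edge_transform(b, sample.int(2, 1))
      twice <- as.numeric(e$matrix %*% (e$matrix %*% s))
      expect_equal(canon(twice), canon(s), tolerance = 1e-9)
    }
  })
})

test_that("the C3 step procedure reproduces the S6 matrices on all 12 transforms", {
  withr::with_seed(33, {
    for (b in 1:6) {
      comp <- ((b - 1) %% 3) + 1
      part <- if (b <= 3) "real" else "imaginary"
      for (v in 1:2) {
        m <- sellingr:::edge_transform(b, v)$matrix
        for (i in 1:100) {
          s <- rnorm(6)
          expect_equal(c3_to_s6(c3_reduce_step(s6_to_c3(s), comp, part, v)),
                       as.numeric(m %*% s), tolerance = 1e-13)
        }
      }
    }
  })
})

test_that("a C3 step negates the positive scalar it eliminates", {
  w <- s6_to_c3(RHOMB60_S6)
  out <- c3_reduce_step(w, 3, "real") # s3 = +0.5 is the target
  expect_equal(Re(out[3]), -0.5, tolerance = 1e-14)
  # a step at a zero boundary value leaves the lattice unchanged; note the
  # output is a new basis (a distinct 24-orbit when the point sits on the
  # boundary), so the check is metric, not canonical-form, equality
  s <- c(0, -1, -2, -3, -4, -5)
  out0 <- c3_to_s6(c3_reduce_step(s6_to_c3(s), 1, "real"))
  expect_true(is_reduced(out0))
  expect_equal(cs6dist(out0, s, input = "s6")$distance, 0, tolerance = 1e-10)
  expect_equal(sellingr:::s6_volume(out0), sellingr:::s6_volume(s), tolerance = 1e-12)
})

test_that("selling_reduce is correct on the worked examples and idempotent", {
  r <- selling_reduce(ORTHO_S6)
  expect_identical(r$reduced, ORTHO_S6)
  expect_identical(r$iterations, 0L)

  r60 <- selling_reduce(RHOMB60_S6)
  expect_true(is_reduced(r60$reduced))
  # brute force over every reduction path: all paths end in one orbit,
  # and selling_reduce's result is in it
  all_canon <- brute_reduce_canonicals(RHOMB60_S6)
  expect_length(all_canon, 1)
  expect_identical(paste(signif(canon(r60$reduced), 10), collapse = ","), all_canon)

  again <- selling_reduce(r60$reduced)
  expect_identical(again$reduced, r60$reduced)
  expect_identical(again$iterations, 0L)
})

test_that("every reduction step decreases -sum(s) by exactly the eliminated scalar", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      base <- reduce_s6(cell_to_s6(sellingr:::random_cell_matrix(1)[1, ]))
      s <- unreduce_random(base, k = sample.int(4, 1))
      r <- selling_reduce(s)
      negsum <- -sum(s)
      for (i in seq_len(r$iterations)) {
        expect_gt(r$ops_applied$eliminated[i], 0)
        negsum <- negsum - r$ops_applied$eliminated[i]
      }
      expect_equal(-sum(r$reduced), negsum, tolerance = 1e-9)
    }
  })
})

test_that("reduction terminates on 10000 random unreduced inputs and preserves volume", {
  withr::with_seed(29, {
    bases <- apply(sellingr:::random_cell_matrix(500), 1,
                   function(p) reduce_s6(cell_to_s6(p)), simplify = FALSE)
    all_reduced <- TRUE
    vol_ok <- TRUE
    for (rep in 1:10000) {
      base <- bases[[(rep - 1) %% 500 + 1]]
      s <- unreduce_random(base, k = sample.int(3, 1))
      r <- selling_reduce(s)
      all_reduced <- all_reduced && is_reduced(r$reduced)
      if (rep %% 50 == 0) {
        rel_err <- abs(sellingr:::s6_volume(r$reduced) / sellingr:::s6_volume(base) - 1)
        vol_ok <- vol_ok && rel_err < 1e-6
      }
    }
    expect_true(all_reduced)
    expect_true(vol_ok)
  })
})

test_that("variant choice and elimination order only change the result by a reflection", {
  withr::with_seed(41, {
    for (rep in 1:30) {
      base <- reduce_s6(cell_to_s6(sellingr:::random_cell_matrix(1)[1, ]))
      s <- unreduce_random(base, k = sample.int(3, 1))
      r1 <- selling_reduce(s, variant = 1)$reduced
      r2 <- selling_reduce(s, variant = 2)$reduced
      expect_equal(canon(r1), canon(r2), tolerance = 1e-8)
      expect_equal(canon(r1), canon(base), tolerance = 1e-8)
    }
  })
})

test_that("selling_reduce reports degenerate input instead of looping", {
  expect_error(selling_reduce(c(1, 1, 1, 1, 1, 1), max_iter = 50), "cap")
})

test_that("is_reduced applies tolerance semantics", {
  expect_true(is_reduced(ORTHO_S6))
  expect_false(is_reduced(RHOMB60_S6))
  expect_true(is_reduced(c(1e-12, -1, -1, -1, -1, -1), tol = 1e-10))
  expect_false(is_reduced(c(1e-8, -1, -1, -1, -1, -1), tol = 1e-10))
})

test_that("canonical presentation collapses each 24-orbit to one representative", {
  withr::with_seed(53, {
    for (rep in 1:30) {
      s <- reduce_s6(cell_to_s6(sellingr:::random_cell_matrix(1)[1, ]))
      canons <- vapply(s6_reflections(), function(op) {
        paste(canonical_presentation(s6_to_c3(apply_sym(op, s))), collapse = "|")
      }, character(1))
      expect_length(unique(canons), 1)
    }
  })
  # fully symmetric vector is its own canonical form
  alleq <- s6_to_c3(rep(-2, 6))
  expect_identical(canonical_presentation(alleq), alleq)
  # idempotence
  w <- canonical_presentation(s6_to_c3(c(0, -1, -3, -2, -5, -4)))
  expect_identical(canonical_presentation(w), w)
  # magnitude-sorted with real <= imaginary on the first two components
  m <- Mod(w)
  expect_true(all(diff(m) >= -1e-12))
  expect_lte(Re(w[1]), Im(w[1]) + 1e-12)
  expect_lte(Re(w[2]), Im(w[2]) + 1e-12)
  expect_error(canonical_presentation(s6_to_c3(RHOMB60_S6)), "reduced")
})

test_that("reduce_cells handles cell and S6 tables in pipelines", {
  out <- reduce_cells(cell_tbl(1, 1, 1, 60, 60, 60))
  expect_identical(out$iterations, 4L)
  expect_true(is_reduced(as.numeric(out[1, paste0("s", 1:6)])))
  back <- reduce_cells(cell_tbl(1, 1, 1, 60, 60, 60), as_cells = TRUE)
  expect_true(all(c("a", "alpha", "iterations") %in% names(back)))
  # same lattice: identical volume
  expect_equal(sellingr:::s6_volume(as.numeric(out[1, paste0("s", 1:6)])),
               sellingr:::s6_volume(cell_to_s6(c(1, 1, 1, 60, 60, 60))),
               tolerance = 1e-9)
})
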