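test_that("snapshot work is the signed final-minus-initial energy difference", {
  fwd <- compute_work(list(eps_ox = 100, eps_red = 90, source_ensemble = "oxidized"))
  expect_equal(fwd$value, -10)
  expect_equal(fwd$direction, "forward")
  bwd <- compute_work(list(eps_ox = 100, eps_red = 90, source_ensemble = "reduced"))
  expect_equal(bwd$value, 10)
  expect_equal(bwd$direction, "backward")
  expect_equal(compute_work(list(eps_ox = 55.5, eps_red = 55.5,
                                 source_ensemble = "oxidized"))$value, 0)
  # antisymmetry under the ensemble label for any energy pair
  set.seed(11)
  for (i in 1:20) {
    eo <- rnorm(1, 0, 200); er <- rnorm(1, 0, 200)
    a <- compute_work(list(eps_ox = eo, eps_red = er, source_ensemble = "oxidized"))
    b <- compute_work(list(eps_ox = eo, eps_red = er, source_ensemble = "reduced"))
    expect_identical(a$value, -b$value)
  }
  expect_error(compute_work(list(eps_ox = NaN, eps_red = 1, frame = 3,
                                 source_ensemble = "oxidized")),
               class = "redoxcb_data_error")
})

make_pairs <- function(n_ox, n_red, system = "sysA") {
  data.frame(system = system,
             replicate = rep(1:2, length.out = n_ox + n_red),
             frame = seq_len(n_ox + n_red),
             source_ensemble = c(rep("oxidized", n_ox), rep("reduced", n_red)),
             eps_ox = seq_len(n_ox + n_red) * 1.5,
             eps_red = seq_len(n_ox + n_red) * 1.1,
             stringsAsFactors = FALSE)
}

test_that("build_workset pools, counts, and guards system labels", {
  ws <- build_workset(make_pairs(3, 2))
  expect_equal(n_forward(ws), 3)
  expect_equal(n_backward(ws), 2)
  expect_equal(ws$label, "sysA")
  expect_warning(empty <- build_workset(data.frame()), "empty")
  expect_equal(n_forward(empty) + n_backward(empty), 0)
  two <- rbind(make_pairs(2, 2, "sysA"), make_pairs(2, 2, "sysB"))
  expect_error(build_workset(two), class = "redoxcb_data_error")
})

test_that("pooling is permutation-stable on the multiset of work values", {
  pairs <- make_pairs(6, 5)
  ws1 <- build_workset(pairs)
  set.seed(3)
  ws2 <- build_workset(pairs[sample(nrow(pairs)), ])
  expect_equal(sort(ws1$forward), sort(ws2$forward))
  expect_equal(sort(ws1$backward), sort(ws2$backward))
  expect_equal(n_forward(ws1), n_forward(ws2))
})

test_that("per-replicate split preserves the pooled multiset", {
  pairs <- make_pairs(6, 6)
  split <- build_workset(pairs, per_replicate = TRUE)
  expect_equal(length(split), 2L)
  pooled <- build_workset(pairs)
  expect_equal(sort(unname(unlist(lapply(split, `[[`, "forward")))), sort(pooled$forward))
})

test_that("energy tables read, normalize aliases, and flag bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("system,replicate,frame,source_ensemble,eps_ox_kjmol,eps_red_kjmol",
               "sysA,1,1,oxidized,100,90",
               "sysA,1,2,oxidised,101,91",
               "sysA,1,1,reduced,100,95",
               "sysA,2,1,Red,99,94"), path)
  df <- read_energy_table(path)
  expect_equal(nrow(df), 4)
  expect_equal(df$source_ensemble, c("oxidized", "oxidized", "reduced", "reduced"))
  expect_equal(df$eps_ox[1], 100)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("system,replicate,frame,source_ensemble,eps_ox_kjmol,eps_red_kjmol",
               "sysA,1,1,oxidized,NaN,90"), bad)
  expect_error(read_energy_table(bad), "line 1", class = "redoxcb_data_error")

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("system,replicate,frame,eps_ox_kjmol,eps_red_kjmol",
               "sysA,1,1,100,90"), miss)
  expect_error(read_energy_table(miss), "source_ensemble",
               class = "redoxcb_data_error")

  unk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("system,replicate,frame,source_ensemble,eps_ox_kjmol,eps_red_kjmol",
               "sysA,1,1,oxydized,100,90"), unk)
  expect_error(read_energy_table(unk), class = "redoxcb_data_error")
})

test_that("energy table write/read round trip preserves records", {
  pairs <- make_pairs(4, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_energy_table(pairs, path)
  back <- read_energy_table(path)
  expect_equal(back$eps_ox, pairs$eps_ox)
  expect_equal(back$source_ensemble, pairs$source_ensemble)
})

test_that("work files round trip bit-exactly and reject junk", {
  set.seed(5)
  ws <- workset(rnorm(30, 10, 3), rnorm(20, -10, 3), make_thermo(298), "sysA")
  pf <- withr::local_tempfile(); pb <- withr::local_tempfile()
  write_work_file(ws, pf, pb)
  back <- read_work_file(pf, pb, make_thermo(298), label = "sysA")
  expect_identical(back$forward, ws$forward)
  expect_identical(back$backward, ws$backward)

  writeLines(c("# only a comment"), pf)
  writeLines(c("1.0", "2.0"), pb)
  one_sided <- read_work_file(pf, pb)
  expect_equal(n_forward(one_sided), 0)
  expect_equal(n_backward(one_sided), 2)

  writeLines("# nothing", pb)
  expect_error(read_work_file(pf, pb), class = "redoxcb_data_error")

  writeLines(c("1.0", "oops", "3.0"), pf)
  expect_error(read_work_file(pf, pb), "line 2", class = "redoxcb_data_error")
})

test_that("xvg dialect skips metadata and pairs files by frame", {
  ox <- withr::local_tempfile(fileext = ".xvg")
  red <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# comment", "@ title \"ox\"", "0 100.0", "1 101.0"), ox)
  writeLines(c("@ legend", "0 90.0", "1 92.5"), red)
  pairs <- read_energy_xvg(ox, red, "oxidized", system = "sysA")
  expect_equal(nrow(pairs), 2)
  ws <- build_workset(pairs)
  expect_equal(ws$forward, c(-10, -8.5))
  writeLines(c("0 90.0"), red)
  expect_error(read_energy_xvg(ox, red, "oxidized"), "mismatch",
               class = "redoxcb_data_error")
  writeLines(c("0 abc"), red)
  expect_error(read_xvg(red), class = "redoxcb_data_error")
})
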