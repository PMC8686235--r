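test_that("default montage has 63 uniquely labelled electrodes with Cz at the origin", {
  m <- default_montage()
  expect_equal(nrow(m), 63)
  expect_false(any(duplicated(m$label)))
  cz <- as.numeric(electrode_positions(m, "Cz"))
  expect_equal(cz, c(0, 0, 0), tolerance = 1e-12)
  # all electrodes on the sphere centered (0, 0, -r)
  r <- attr(m, "radius")
  d <- sqrt(m$x^2 + m$y^2 + (m$z + r)^2)
  expect_true(all(abs(d - r) < 1e-9))
  # left/right symmetry of homologous pairs
  expect_equal(unlist(m[m$label == "C4", c("x", "y", "z")]),
               unlist(m[m$label == "C3", c("x", "y", "z")]) * c(-1, 1, 1),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("electrode position files round-trip and invalid files are rejected", {
  m <- default_montage()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_montage(m, path)
  m2 <- load_montage(path)
  expect_equal(m2$label, m$label)
  expect_equal(m2$x, m$x, tolerance = 1e-8)
  expect_equal(attr(m2, "fiducials")$label, c("NAS", "INI", "LPA", "RPA"))

  nine <- m[m$label %in% c("FC1", "FC2", "C1", "Cz", "C2", "C3", "C4", "CP1", "CP2"), ]
  write_montage(structure(nine, class = class(m)), path)
  expect_equal(nrow(load_montage(path)), 9)

  writeLines(c("C3\t1\t2\t3", "C3\t4\t5\t6", "Cz\t0\t0\t0"), path)
  expect_error(load_montage(path), "C3")
  writeLines(c("C3\t1\t2\t3", "C4\t1\t2"), path)
  expect_error(load_montage(path), "line 2")
  writeLines(c("C3\t1\t2\t3", "C4\t-1\t2\t3"), path)
  expect_error(load_montage(path), "Cz")
})

test_that("to_cz_frame is a rigid transform mapping Cz to the origin", {
  m <- default_montage()
  pts <- electrode_positions(m)

  # identity fiducials: points already in the Cz frame are unchanged
  expect_equal(to_cz_frame(pts, m), unname(pts), ignore_attr = TRUE, tolerance = 1e-12)

  # arbitrary rotation + translation of the whole digitization
  th <- 0.7; ph <- -0.3
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  R <- Rz %*% Rx; shift <- c(3, -2, 11)
  raw <- t(R %*% t(pts)) + rep(shift, each = nrow(pts))
  m_raw <- m
  m_raw$x <- raw[, 1]; m_raw$y <- raw[, 2]; m_raw$z <- raw[, 3]
  fid <- attr(m, "fiducials")
  fid_raw <- as.matrix(fid[, c("x", "y", "z")]) %*% t(R) + rep(shift, each = 4)
  fid$x <- fid_raw[, 1]; fid$y <- fid_raw[, 2]; fid$z <- fid_raw[, 3]
  attr(m_raw, "fiducials") <- fid

  rec <- to_cz_frame(raw, m_raw)
  expect_equal(rec, unname(pts), ignore_attr = TRUE, tolerance = 1e-9)
  # the digitized Cz itself maps to the origin
  expect_equal(as.numeric(to_cz_frame(raw[m$label == "Cz", ], m_raw)),
               c(0, 0, 0), tolerance = 1e-9)
  # isometry: pairwise distances preserved to 1e-9 relative
  d0 <- dist(pts); d1 <- dist(rec)
  expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-12)), 1e-9)

  # degenerate fiducials
  fid_bad <- attr(m, "fiducials")
  fid_bad[fid_bad$label == "NAS", c("x", "y", "z")] <- list(0, 0, -9)
  m_bad <- m; attr(m_bad, "fiducials") <- fid_bad
  expect_error(to_cz_frame(pts, m_bad), "collinear|degenerate")
})

test_that("channel sets have the fixed counts, nest, and resolve per-hand variants", {
  m <- default_montage()
  sets <- default_channel_sets()
  expect_length(channel_set(m, "Ch_Set1"), 63)
  expect_length(channel_set(m, "Ch_Set5"), 9)
  expect_length(channel_set(m, "Ch_Set4", hand = "right"), 17)
  expect_length(channel_set(m, "Ch_Set4", hand = "left"), 17)
  expect_error(channel_set(m, "Ch_Set4"), "hand")
  expect_error(channel_set(m, "Ch_SetX"), "Ch_Set1")

  labs <- lapply(paste0("Ch_Set", 1:5), function(s) sets[[s]]$labels)
  for (i in 2:5) expect_true(all(labs[[i]] %in% labs[[i - 1]]))
  # every selected label indexes exactly one electrode
  for (s in paste0("Ch_Set", c(1, 2, 3, 5))) {
    sel <- channel_set(m, s)
    expect_true(all(table(match(sel, m$label)) == 1))
  }
  # deterministic
  expect_identical(channel_set(m, "Ch_Set3"), channel_set(m, "Ch_Set3"))
})

test_that("channel-set YAML config round-trips and feeds selection", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "MySet:",
    "  - C3", "  - Cz", "  - C4",
    "Handed:",
    "  labels: [C3, C4]",
    "  per_hand:",
    "    left: [C4, C2]",
    "    right: [C3, C1]"
  ), path)
  sets <- read_channel_sets(path)
  m <- default_montage()
  expect_equal(as.character(channel_set(m, "MySet", sets = sets)), c("C3", "Cz", "C4"))
  expect_equal(as.character(channel_set(m, "Handed", hand = "right", sets = sets)),
               c("C3", "C1"))
})
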