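test_that("fidelity mapping is geometric, monotone and bounded", {
  expect_equal(fidelity_to_cells(1, 8000, 160000), 8000)
  expect_equal(fidelity_to_cells(100, 8000, 160000), 160000)
  # closed form evaluated independently
  expect_equal(fidelity_to_cells(50, 8000, 160000),
               round(8000 * (160000 / 8000)^(49 / 99)))
  n <- fidelity_to_cells(1:100, 8000, 160000)
  expect_true(all(diff(n) > 0))
  expect_error(fidelity_to_cells(0), "\\[1, 100\\]")
  expect_error(fidelity_to_cells(101), "\\[1, 100\\]")
  expect_error(fidelity_to_cells(50, 100, 100), "n_min < n_max")
})

test_that("build_mesh hits the cell target and produces valid hexes", {
  geom <- make_stenosed_vessel(lesion_spec(60), 64, 32)
  prev <- 0
  for (pct in c(10, 25, 50, 75, 100)) {
    m <- build_mesh(geom, pct, n_min = 300, n_max = 3000)
    target <- fidelity_to_cells(pct, 300, 3000)
    expect_lt(abs(m$cell_count - target) / target, 0.15)
    expect_gt(m$cell_count, prev)
    prev <- m$cell_count
    expect_true(all(m$cell_volume > 0))
  }
  q <- mesh_quality(build_mesh(geom, 10, n_min = 300, n_max = 3000))
  expect_gt(q$jacobian["min"], 0)
})

test_that("mesh volume converges to the analytic tube volume", {
  set.seed(911)
  # random specs at full fidelity of a desk budget: < 1% volume error
  for (i in 1:10) {
    sp <- stenosis_spec(runif(1, 2.5, 4), runif(1, 30, 90),
                        runif(1, 6, 14), runif(1, 12, 18),
                        vessel_length = 30)
    geom <- make_stenosed_vessel(sp, 64, 32)
    m <- build_mesh(geom, 100, n_min = 1000, n_max = 10000)
    rel <- abs(mesh_volume_mm3(m) - analytic_volume_mm3(geom)) /
      analytic_volume_mm3(geom)
    expect_lt(rel, 0.01)
  }
  # non-strict monotone volume-error decrease across the five fidelities
  geom <- make_stenosed_vessel(lesion_spec(60), 64, 32)
  va <- analytic_volume_mm3(geom)
  err <- vapply(c(10, 25, 50, 75, 100), function(p)
    abs(mesh_volume_mm3(build_mesh(geom, p, n_min = 300, n_max = 3000)) - va),
    numeric(1))
  expect_true(all(diff(err) <= 1e-9))
})

test_that("boundary tags partition the boundary and wall cells are graded", {
  geom <- make_stenosed_vessel(cylinder_spec(), 48, 24)
  m <- build_mesh(geom, 50, n_min = 300, n_max = 3000)
  boundary <- is.na(m$neigh)
  expect_true(all(m$btype[boundary] %in% 1:3))
  expect_true(all(m$btype[!boundary] == 0L))
  expect_equal(sum(m$btype == 1L), m$n_cross)  # inlet cap
  expect_equal(sum(m$btype == 2L), m$n_cross)  # outlet cap
  # no orphan nodes
  expect_setequal(sort(unique(as.vector(m$cells))), seq_len(nrow(m$nodes)))
  # wall grading: outermost radial template interval thinner than interior
  tpl <- vffrsim:::.butterfly_template(2, 5)
  # template radial fractions: reconstruct widths from a ray
  expect_gt(tpl$n_wall_edges, 0)
  m_fine <- build_mesh(geom, 100, n_min = 300, n_max = 3000)
  wall_faces <- which(m_fine$btype == 3L)
  wall_cells <- m_fine$owner[wall_faces]
  interior_cells <- setdiff(seq_len(m_fine$cell_count),
                            unique(m_fine$owner[m_fine$btype != 0L]))
  expect_lt(median(m_fine$cell_volume[wall_cells]),
            median(m_fine$cell_volume[interior_cells]))
})

test_that("meshing is deterministic", {
  geom <- make_stenosed_vessel(lesion_spec(45), 48, 24)
  m1 <- build_mesh(geom, 50, n_min = 300, n_max = 3000)
  m2 <- build_mesh(geom, 50, n_min = 300, n_max = 3000)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$cells, m2$cells)
  expect_identical(m1$Sf, m2$Sf)
})

test_that("a deliberately inverted cell is flagged by mesh_quality", {
  geom <- make_stenosed_vessel(cylinder_spec(), 48, 24)
  m <- build_mesh(geom, 10, n_min = 300, n_max = 3000)
  q0 <- mesh_quality(m)
  expect_equal(q0$n_flagged, 0L)
  # swap the top and bottom quads of one hex: inverted connectivity
  m$cells[17, ] <- m$cells[17, c(5:8, 1:4)]
  q1 <- mesh_quality(m)
  expect_equal(q1$flagged_cells, 17L)
  expect_lt(q1$jacobian["min"], 0)
})

test_that("vtu export writes a readable XML unstructured grid", {
  geom <- make_stenosed_vessel(cylinder_spec(), 32, 16)
  m <- build_mesh(geom, 10, n_min = 300, n_max = 3000)
  p <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(m, p, cell_data = list(vol = m$cell_volume))
  doc <- xml2::read_xml(p)
  expect_equal(xml2::xml_name(doc), "VTKFile")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
               m$cell_count)
})
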