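test_that("triangle cells sit at the documented centers", {
  n <- 8
  adj <- triangle_coords(0, 1, n)
  expect_equal(unname(adj$center), cbind(0.5, -0.5))
  apex <- triangle_coords(0, n - 1, n)
  expect_equal(unname(apex$center), cbind((n - 1) / 2, -(n - 1) / 2))
  expect_error(triangle_coords(3, 3, n), class = "ldassoc_usage_error")
  expect_error(triangle_coords(0, n, n), class = "ldassoc_usage_error")
})

test_that("diamond cells tile the triangle without overlap", {
  for (n in c(4, 11, 30)) {
    pr <- t(utils::combn(n, 2)) - 1L
    tc <- triangle_coords(pr[, 1], pr[, 2], n)
    expect_equal(nrow(tc$center), n * (n - 1) / 2)
    # rotating 45 degrees maps centers to the integer grid (u, v) = (i, j);
    # distinct integer points => Chebyshev distance >= 1 => interiors disjoint
    u <- tc$center[, "x"] + tc$center[, "y"]
    v <- tc$center[, "x"] - tc$center[, "y"]
    expect_equal(u, as.numeric(pr[, 1]))
    expect_equal(v, as.numeric(pr[, 2]))
    expect_false(any(duplicated(cbind(u, v))))
    # vertices stay inside the triangle's bounding region
    expect_true(all(tc$x >= -0.5 & tc$x <= n - 0.5))
    expect_true(all(tc$y <= 0 + 0.5))
  }
})

test_that("ld_color bins values by first upper bound at or above", {
  sc <- ld_color_scale("c02", "c04", "c06", "c08", "c10")
  expect_equal(ld_color(0.35, sc), "c04")
  expect_equal(ld_color(0, sc), "c02")
  expect_equal(ld_color(0.2, sc), "c02")    # (0, 0.2] is the first bin
  expect_equal(ld_color(1, sc), "c10")
  expect_equal(ld_color(NA, sc, na_color = "x"), "x")
  expect_error(ld_color(1.2, sc), class = "ldassoc_usage_error")
  # changing colors never changes the bin index
  gray <- ld_color_scale("gray81", "gray61", "gray41", "gray11", "gray1")
  v <- c(0, 0.15, 0.2000001, 0.55, 0.8, 0.99)
  expect_equal(match(ld_color(v, gray), gray$colors),
               match(ld_color(v, sc), sc$colors))
})

test_that("figure geometry is deterministic and order-isomorphic", {
  scope <- fx_scope()
  ld <- ld_matrix(fx_panel())
  lead_ld <- lead_snp_ld(fx_panel(), scope$lead)
  s1 <- build_figure_spec(scope, ld, lead_ld)
  s2 <- build_figure_spec(scope, ld, lead_ld)
  expect_identical(s1, s2)
  # marker order by genomic x == marker order by LD index
  expect_false(is.unsorted(s1$markers$x))
  expect_false(is.unsorted(s1$ld$markers$pos))
  expect_equal(order(s1$ld$top_x), seq_len(s1$ld$n))
  # geometry finite
  expect_true(all(is.finite(s1$markers$x)) && all(is.finite(s1$markers$y)))
})

test_that("linking lines follow the significant set by default", {
  scope <- fx_scope(threshold = 5)
  ld <- ld_matrix(fx_panel())
  spec <- build_figure_spec(scope, ld, NULL)
  nsig <- length(scope$significant)
  expect_gt(nsig, 0)
  expect_equal(sum(spec$links$segment == "A"), nsig)
  expect_equal(sum(spec$links$segment == "B"), nsig)
  # all endpoints inside their layers' vertical extents
  ylims <- range(c(spec$layers$y_lo, spec$layers$y_hi))
  expect_true(all(spec$links$y0 >= ylims[1] & spec$links$y0 <= ylims[2]))
  expect_true(all(spec$links$y1 >= ylims[1] & spec$links$y1 <= ylims[2]))
})

test_that("link2gene/link2LD override selections independently", {
  scope <- fx_scope(threshold = 5)
  ld <- ld_matrix(fx_panel())
  one <- scope$significant[1]
  st <- plot_style(link2LD = one)
  spec <- build_figure_spec(scope, ld, NULL, style = st)
  expect_equal(sum(spec$links$segment == "B"), 1L)
  expect_equal(sum(spec$links$segment == "A"), length(scope$significant))
  expect_warning(
    build_figure_spec(scope, ld, NULL,
                      style = plot_style(link2gene = "not_a_marker")),
    "outside scope")
})

test_that("markers unmatched in a different LD panel link only to the gene track", {
  scope <- fx_scope(threshold = 5)
  ld_panel <- fx_panel2()
  idx <- panel_idx <- which(ld_panel$markers$chrom == scope$region$chrom &
                            ld_panel$markers$pos >= scope$region$left &
                            ld_panel$markers$pos <= scope$region$right)
  sub <- gt_subset(ld_panel, idx)
  ld <- ld_matrix(sub)
  matched <- match_markers(scope$assoc, sub)
  expect_gt(attr(matched, "n_unmatched"), 0)
  spec <- build_figure_spec(scope, ld, NULL, matched = matched)
  sig <- scope$significant
  matched_sig <- sig[!is.na(matched[match(sig, scope$assoc$marker)])]
  expect_equal(sum(spec$links$segment == "A"), length(sig))
  expect_equal(sum(spec$links$segment == "B"), length(matched_sig))
})

test_that("highlight selectors restyle points and report misses", {
  scope <- fx_scope()
  hi <- data.frame(marker = scope$assoc$marker[3], pch = 17L,
                   color = "purple", size = 2)
  spec <- build_figure_spec(scope, NULL, NULL,
                            style = plot_style(highlight = hi),
                            triangleLD = FALSE)
  i <- match(hi$marker, spec$markers$name)
  expect_equal(spec$markers$pch[i], 17L)
  expect_equal(spec$markers$color[i], "purple")
  expect_warning(
    build_figure_spec(scope, NULL, NULL, triangleLD = FALSE,
                      style = plot_style(highlight = data.frame(
                        marker = "nope", pch = 1L))),
    "matched no")
})

test_that("label repulsion is deterministic and separates overlaps", {
  x <- c(0.5, 0.5, 0.52)
  y <- c(0.8, 0.8, 0.81)
  y1 <- ldassoc:::repel_labels(x, y)
  y2 <- ldassoc:::repel_labels(x, y)
  expect_identical(y1, y2)
  d <- as.numeric(dist(cbind(x * 0, y1)))
  expect_true(all(d[abs(outer(x, x, "-"))[lower.tri(diag(3))] < 0.08] > 0.03))
})
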