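test_that("region labels always partition the grid", {
  lib <- generateImplantLibrary(6, seed = 3, grid = GridSpec(48, 24),
                                callusWidth = 2)
  for (d in lib) {
    tab <- table(factor(regionMap(d), levels = regionCodes()))
    expect_equal(sum(tab), 48 * 24)
    expect_true(sum(implantMask(d)) > 0)
    expect_true(sum(callusMask(d)) > 0)
  }
})

test_that("degenerate thread depth rasterizes to a straight cylinder", {
  p <- ImplantParams(bodyLength = 20, bodyRadius = 5, threadPitch = 6,
                     threadDepth = 0)
  d <- buildImplantProfile(p, GridSpec(40, 20))
  expect_equal(sum(implantMask(d)), 20 * 5)
  expect_true(is.na(firstThreadRow(d)))
})

test_that("the default grid matches the 210 x 52 frame", {
  p <- ImplantParams(bodyLength = 170, bodyRadius = 9, threadPitch = 10,
                     threadDepth = 4)
  d <- buildImplantProfile(p, GridSpec())
  expect_identical(dim(regionMap(d)), c(210L, 52L))
})

test_that("rasterization agrees with a point-in-polygon oracle", {
  grid <- GridSpec(64, 32)
  cases <- list(
    ImplantParams(40, 6, 8, 3, "triangular"),
    ImplantParams(44, 8, 10, c(2, 4), "trapezoidal", "pointed",
                  collarHeight = 3),
    ImplantParams(36, 7, 6, 3.5, "buttress", "rounded"))
  for (p in cases) {
    d <- buildImplantProfile(p, grid)
    poly <- profilePolygon(p)
    ctr <- expand.grid(i = seq_len(64), j = seq_len(32))
    inPoly <- pointInPolygon(ctr$j - 0.5, ctr$i - 0.5, poly$x, poly$y)
    oracle <- matrix(inPoly, 64, 32)
    expect_identical(implantMask(d), oracle)
  }
})

test_that("geometry exceeding the grid fails naming the dimension", {
  expect_error(buildImplantProfile(ImplantParams(100, 5, 8, 2),
                                   GridSpec(40, 20)),
               "rows")
  expect_error(buildImplantProfile(ImplantParams(20, 18, 8, 1),
                                   GridSpec(40, 20)),
               "columns")
})

test_that("segment swap is local, involutive and splice-exact", {
  g <- GridSpec(64, 32)
  dA <- buildImplantProfile(ImplantParams(40, 6, 8, 3), g)
  dB <- buildImplantProfile(ImplantParams(40, 8, 10, 2, "buttress"), g)

  ## empty swap returns the inputs
  h0 <- swapSegment(dA, dB, c(20, 20))
  expect_identical(regionMap(h0$aba), regionMap(dA))
  expect_identical(regionMap(h0$bab), regionMap(dB))

  rr <- c(14, 27)                       # middle third, 0-based half-open
  hy <- swapSegment(dA, dB, rr)

  ## splicing oracle: manual cut-and-paste of the label arrays
  rows <- (rr[1] + 1):rr[2]
  manA <- regionMap(dA); manA[rows, ] <- regionMap(dB)[rows, ]
  manB <- regionMap(dB); manB[rows, ] <- regionMap(dA)[rows, ]
  expect_identical(regionMap(hy$aba), manA)
  expect_identical(regionMap(hy$bab), manB)

  ## no pixel outside the range changes
  expect_identical(regionMap(hy$aba)[-rows, ], regionMap(dA)[-rows, ])
  expect_identical(regionMap(hy$bab)[-rows, ], regionMap(dB)[-rows, ])

  ## involution recovers the originals (masks re-derived identically)
  back <- swapSegment(hy$aba, hy$bab, rr)
  expect_identical(regionMap(back$aba), regionMap(dA))
  expect_identical(regionMap(back$bab), regionMap(dB))
  expect_identical(cellOriginMask(back$aba), cellOriginMask(dA))
  expect_identical(loadMask(back$bab), loadMask(dB))
  expect_identical(firstThreadRow(back$aba), firstThreadRow(dA))

  ## a range outside the implants' common extent is rejected
  expect_error(swapSegment(dA, dB, c(0, 10)), "axial extent")
})

test_that("implant library generation is deterministic and seed-sensitive", {
  g <- GridSpec(48, 24)
  a1 <- generateImplantLibrary(3, seed = 9, grid = g, callusWidth = 2)
  a2 <- generateImplantLibrary(3, seed = 9, grid = g, callusWidth = 2)
  b <- generateImplantLibrary(3, seed = 10, grid = g, callusWidth = 2)
  for (i in 1:3)
    expect_identical(regionMap(a1[[i]]), regionMap(a2[[i]]))
  expect_true(any(vapply(1:3, function(i)
    !identical(regionMap(a1[[i]]), regionMap(b[[i]])), logical(1))))
})

test_that("a 65-case library at full scale is fully valid", {
  lib <- generateImplantLibrary(65, seed = 7)
  expect_length(lib, 65)
  for (d in lib) expect_true(isTRUE(validObject(d, test = TRUE)))
})
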