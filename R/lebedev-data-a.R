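# Lebedev-Laikov quadrature nodes on the unit sphere (octahedral symmetry),
# normalized so that weights sum to 1.  Nodes of algebraic precision p
# integrate spherical harmonics exactly up to degree p.

.lebedev_raw[["6"]] <- list(precision = 3L,
  xyz = matrix(c(
    1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    -1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, -1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, 1.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, -1.0000000000000000e+00
  ), ncol = 3L, byrow = TRUE),
  w = c(
    1.6666666666666666e-01, 1.6666666666666666e-01, 1.6666666666666666e-01, 1.6666666666666666e-01,
    1.6666666666666666e-01, 1.6666666666666666e-01
  ))
.lebedev_raw[["26"]] <- list(precision = 7L,
  xyz = matrix(c(
    1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    -1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, -1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, 1.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, -1.0000000000000000e+00,
    0.0000000000000000e+00, 7.0710678118654757e-01, 7.0710678118654757e-01,
    0.0000000000000000e+00, -7.0710678118654757e-01, 7.0710678118654757e-01,
    0.0000000000000000e+00, 7.0710678118654757e-01, -7.0710678118654757e-01,
    0.0000000000000000e+00, -7.0710678118654757e-01, -7.0710678118654757e-01,
    7.0710678118654757e-01, 0.0000000000000000e+00, 7.0710678118654757e-01,
    7.0710678118654757e-01, 0.0000000000000000e+00, -7.0710678118654757e-01,
    -7.0710678118654757e-01, 0.0000000000000000e+00, 7.0710678118654757e-01,
    -7.0710678118654757e-01, 0.0000000000000000e+00, -7.0710678118654757e-01,
    7.0710678118654757e-01, 7.0710678118654757e-01, 0.0000000000000000e+00,
    -7.0710678118654757e-01, 7.0710678118654757e-01, 0.0000000000000000e+00,
    7.0710678118654757e-01, -7.0710678118654757e-01, 0.0000000000000000e+00,
    -7.0710678118654757e-01, -7.0710678118654757e-01, 0.0000000000000000e+00,
    5.7735026918962573e-01, 5.7735026918962573e-01, 5.7735026918962573e-01,
    -5.7735026918962573e-01, 5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, -5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, 5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, -5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, -5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, 5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, -5.7735026918962573e-01, -5.7735026918962573e-01
  ), ncol = 3L, byrow = TRUE),
  w = c(
    4.7619047619047623e-02, 4.7619047619047623e-02, 4.7619047619047623e-02, 4.7619047619047623e-02,
    4.7619047619047623e-02, 4.7619047619047623e-02, 3.8095238095238099e-02, 3.8095238095238099e-02,
    3.8095238095238099e-02, 3.8095238095238099e-02, 3.8095238095238099e-02, 3.8095238095238099e-02,
    3.8095238095238099e-02, 3.8095238095238099e-02, 3.8095238095238099e-02, 3.8095238095238099e-02,
    3.8095238095238099e-02, 3.8095238095238099e-02, 3.2142857142857140e-02, 3.2142857142857140e-02,
    3.2142857142857140e-02, 3.2142857142857140e-02, 3.2142857142857140e-02, 3.2142857142857140e-02,
    3.2142857142857140e-02, 3.2142857142857140e-02
  ))
.lebedev_raw[["50"]] <- list(precision = 11L,
  xyz = matrix(c(
    1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    -1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, -1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, 1.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, -1.0000000000000000e+00,
    0.0000000000000000e+00, 7.0710678118654757e-01, 7.0710678118654757e-01,
    0.0000000000000000e+00, -7.0710678118654757e-01, 7.0710678118654757e-01,
    0.0000000000000000e+00, 7.0710678118654757e-01, -7.0710678118654757e-01,
    0.0000000000000000e+00, -7.0710678118654757e-01, -7.0710678118654757e-01,
    7.0710678118654757e-01, 0.0000000000000000e+00, 7.0710678118654757e-01,
    7.0710678118654757e-01, 0.0000000000000000e+00, -7.0710678118654757e-01,
    -7.0710678118654757e-01, 0.0000000000000000e+00, 7.0710678118654757e-01,
    -7.0710678118654757e-01, 0.0000000000000000e+00, -7.0710678118654757e-01,
    7.0710678118654757e-01, 7.0710678118654757e-01, 0.0000000000000000e+00,
    -7.0710678118654757e-01, 7.0710678118654757e-01, 0.0000000000000000e+00,
    7.0710678118654757e-01, -7.0710678118654757e-01, 0.0000000000000000e+00,
    -7.0710678118654757e-01, -7.0710678118654757e-01, 0.0000000000000000e+00,
    5.7735026918962573e-01, 5.7735026918962573e-01, 5.7735026918962573e-01,
    -5.7735026918962573e-01, 5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, -5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, 5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, -5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, -5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, 5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, -5.7735026918962573e-01, -5.7735026918962573e-01,
    3.0151134457776357e-01, 3.0151134457776357e-01, 9.0453403373329089e-01,
    -3.0151134457776357e-01, 3.0151134457776357e-01, 9.0453403373329089e-01,
    3.0151134457776357e-01, -3.0151134457776357e-01, 9.0453403373329089e-01,
    3.0151134457776357e-01, 3.0151134457776357e-01, -9.0453403373329089e-01,
    -3.0151134457776357e-01, -3.0151134457776357e-01, 9.0453403373329089e-01,
    -3.0151134457776357e-01, 3.0151134457776357e-01, -9.0453403373329089e-01,
    3.0151134457776357e-01, -3.0151134457776357e-01, -9.0453403373329089e-01,
    -3.0151134457776357e-01, -3.0151134457776357e-01, -9.0453403373329089e-01,
    -3.0151134457776357e-01, 9.0453403373329089e-01, 3.0151134457776357e-01,
    3.0151134457776357e-01, -9.0453403373329089e-01, 3.0151134457776357e-01,
    3.0151134457776357e-01, 9.0453403373329089e-01, -3.0151134457776357e-01,
    -3.0151134457776357e-01, -9.0453403373329089e-01, 3.0151134457776357e-01,
    -3.0151134457776357e-01, 9.0453403373329089e-01, -3.0151134457776357e-01,
    3.0151134457776357e-01, -9.0453403373329089e-01, -3.0151134457776357e-01,
    -3.0151134457776357e-01, -9.0453403373329089e-01, -3.0151134457776357e-01,
    3.0151134457776357e-01, 9.0453403373329089e-01, 3.0151134457776357e-01,
    9.0453403373329089e-01, 3.0151134457776357e-01, 3.0151134457776357e-01,
    -9.0453403373329089e-01, 3.0151134457776357e-01, 3.0151134457776357e-01,
    9.0453403373329089e-01, -3.0151134457776357e-01, 3.0151134457776357e-01,
    9.0453403373329089e-01, 3.0151134457776357e-01, -3.0151134457776357e-01,
    -9.0453403373329089e-01, -3.0151134457776357e-01, 3.0151134457776357e-01,
    -9.0453403373329089e-01, 3.0151134457776357e-01, -3.0151134457776357e-01,
    9.0453403373329089e-01, -3.0151134457776357e-01, -3.0151134457776357e-01,
    -9.0453403373329089e-01, -3.0151134457776357e-01, -3.0151134457776357e-01
  ), ncol = 3L, byrow = TRUE),
  w = c(
    1.2698412698412700e-02, 1.2698412698412700e-02, 1.2698412698412700e-02, 1.2698412698412700e-02,
    1.2698412698412700e-02, 1.2698412698412700e-02, 2.2574955908289240e-02, 2.2574955908289240e-02,
    2.2574955908289240e-02, 2.2574955908289240e-02, 2.2574955908289240e-02, 2.2574955908289240e-02,
    2.2574955908289240e-02, 2.2574955908289240e-02, 2.2574955908289240e-02, 2.2574955908289240e-02,
    2.2574955908289240e-02, 2.2574955908289240e-02, 2.1093750000000001e-02, 2.1093750000000001e-02,
    2.1093750000000001e-02, 2.1093750000000001e-02, 2.1093750000000001e-02, 2.1093750000000001e-02,
    2.1093750000000001e-02, 2.1093750000000001e-02, 2.0173335537918870e-02, 2.0173335537918870e-02,
    2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02,
    2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02,
    2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02,
    2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02,
    2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02, 2.0173335537918870e-02,
    2.0173335537918870e-02, 2.0173335537918870e-02
  ))
.lebedev_raw[["110"]] <- list(precision = 17L,
  xyz = matrix(c(
    1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    -1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, -1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, 1.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, -1.0000000000000000e+00,
    5.7735026918962573e-01, 5.7735026918962573e-01, 5.7735026918962573e-01,
    -5.7735026918962573e-01, 5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, -5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, 5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, -5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, -5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, 5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, -5.7735026918962573e-01, -5.7735026918962573e-01,
    1.8511563534473621e-01, 1.8511563534473621e-01, 9.6512403508659406e-01,
    -1.8511563534473621e-01, 1.8511563534473621e-01, 9.6512403508659406e-01,
    1.8511563534473621e-01, -1.8511563534473621e-01, 9.6512403508659406e-01,
    1.8511563534473621e-01, 1.8511563534473621e-01, -9.6512403508659406e-01,
    -1.8511563534473621e-01, -1.8511563534473621e-01, 9.6512403508659406e-01,
    -1.8511563534473621e-01, 1.8511563534473621e-01, -9.6512403508659406e-01,
    1.8511563534473621e-01, -1.8511563534473621e-01, -9.6512403508659406e-01,
    -1.8511563534473621e-01, -1.8511563534473621e-01, -9.6512403508659406e-01,
    -1.8511563534473621e-01, 9.6512403508659406e-01, 1.8511563534473621e-01,
    1.8511563534473621e-01, -9.6512403508659406e-01, 1.8511563534473621e-01,
    1.8511563534473621e-01, 9.6512403508659406e-01, -1.8511563534473621e-01,
    -1.8511563534473621e-01, -9.6512403508659406e-01, 1.8511563534473621e-01,
    -1.8511563534473621e-01, 9.6512403508659406e-01, -1.8511563534473621e-01,
    1.8511563534473621e-01, -9.6512403508659406e-01, -1.8511563534473621e-01,
    -1.8511563534473621e-01, -9.6512403508659406e-01, -1.8511563534473621e-01,
    1.8511563534473621e-01, 9.6512403508659406e-01, 1.8511563534473621e-01,
    9.6512403508659406e-01, 1.8511563534473621e-01, 1.8511563534473621e-01,
    -9.6512403508659406e-01, 1.8511563534473621e-01, 1.8511563534473621e-01,
    9.6512403508659406e-01, -1.8511563534473621e-01, 1.8511563534473621e-01,
    9.6512403508659406e-01, 1.8511563534473621e-01, -1.8511563534473621e-01,
    -9.6512403508659406e-01, -1.8511563534473621e-01, 1.8511563534473621e-01,
    -9.6512403508659406e-01, 1.8511563534473621e-01, -1.8511563534473621e-01,
    9.6512403508659406e-01, -1.8511563534473621e-01, -1.8511563534473621e-01,
    -9.6512403508659406e-01, -1.8511563534473621e-01, -1.8511563534473621e-01,
    6.9042104838229224e-01, 6.9042104838229224e-01, 2.1595729184584844e-01,
    -6.9042104838229224e-01, 6.9042104838229224e-01, 2.1595729184584844e-01,
    6.9042104838229224e-01, -6.9042104838229224e-01, 2.1595729184584844e-01,
    6.9042104838229224e-01, 6.9042104838229224e-01, -2.1595729184584844e-01,
    -6.9042104838229224e-01, -6.9042104838229224e-01, 2.1595729184584844e-01,
    -6.9042104838229224e-01, 6.9042104838229224e-01, -2.1595729184584844e-01,
    6.9042104838229224e-01, -6.9042104838229224e-01, -2.1595729184584844e-01,
    -6.9042104838229224e-01, -6.9042104838229224e-01, -2.1595729184584844e-01,
    -6.9042104838229224e-01, 2.1595729184584844e-01, 6.9042104838229224e-01,
    6.9042104838229224e-01, -2.1595729184584844e-01, 6.9042104838229224e-01,
    6.9042104838229224e-01, 2.1595729184584844e-01, -6.9042104838229224e-01,
    -6.9042104838229224e-01, -2.1595729184584844e-01, 6.9042104838229224e-01,
    -6.9042104838229224e-01, 2.1595729184584844e-01, -6.9042104838229224e-01,
    6.9042104838229224e-01, -2.1595729184584844e-01, -6.9042104838229224e-01,
    -6.9042104838229224e-01, -2.1595729184584844e-01, -6.9042104838229224e-01,
    6.9042104838229224e-01, 2.1595729184584844e-01, 6.9042104838229224e-01,
    2.1595729184584844e-01, 6.9042104838229224e-01, 6.9042104838229224e-01,
    -2.1595729184584844e-01, 6.9042104838229224e-01, 6.9042104838229224e-01,
    2.1595729184584844e-01, -6.9042104838229224e-01, 6.9042104838229224e-01,
    2.1595729184584844e-01, 6.9042104838229224e-01, -6.9042104838229224e-01,
    -2.1595729184584844e-01, -6.9042104838229224e-01, 6.9042104838229224e-01,
    -2.1595729184584844e-01, 6.9042104838229224e-01, -6.9042104838229224e-01,
    2.1595729184584844e-01, -6.9042104838229224e-01, -6.9042104838229224e-01,
    -2.1595729184584844e-01, -6.9042104838229224e-01, -6.9042104838229224e-01,
    3.9568947305594188e-01, 3.9568947305594188e-01, 8.2876998125259227e-01,
    -3.9568947305594188e-01, 3.9568947305594188e-01, 8.2876998125259227e-01,
    3.9568947305594188e-01, -3.9568947305594188e-01, 8.2876998125259227e-01,
    3.9568947305594188e-01, 3.9568947305594188e-01, -8.2876998125259227e-01,
    -3.9568947305594188e-01, -3.9568947305594188e-01, 8.2876998125259227e-01,
    -3.9568947305594188e-01, 3.9568947305594188e-01, -8.2876998125259227e-01,
    3.9568947305594188e-01, -3.9568947305594188e-01, -8.2876998125259227e-01,
    -3.9568947305594188e-01, -3.9568947305594188e-01, -8.2876998125259227e-01,
    -3.9568947305594188e-01, 8.2876998125259227e-01, 3.9568947305594188e-01,
    3.9568947305594188e-01, -8.2876998125259227e-01, 3.9568947305594188e-01,
    3.9568947305594188e-01, 8.2876998125259227e-01, -3.9568947305594188e-01,
    -3.9568947305594188e-01, -8.2876998125259227e-01, 3.9568947305594188e-01,
    -3.9568947305594188e-01, 8.2876998125259227e-01, -3.9568947305594188e-01,
    3.9568947305594188e-01, -8.2876998125259227e-01, -3.9568947305594188e-01,
    -3.9568947305594188e-01, -8.2876998125259227e-01, -3.9568947305594188e-01,
    3.9568947305594188e-01, 8.2876998125259227e-01, 3.9568947305594188e-01,
    8.2876998125259227e-01, 3.9568947305594188e-01, 3.9568947305594188e-01,
    -8.2876998125259227e-01, 3.9568947305594188e-01, 3.9568947305594188e-01,
    8.2876998125259227e-01, -3.9568947305594188e-01, 3.9568947305594188e-01,
    8.2876998125259227e-01, 3.9568947305594188e-01, -3.9568947305594188e-01,
    -8.2876998125259227e-01, -3.9568947305594188e-01, 3.9568947305594188e-01,
    -8.2876998125259227e-01, 3.9568947305594188e-01, -3.9568947305594188e-01,
    8.2876998125259227e-01, -3.9568947305594188e-01, -3.9568947305594188e-01,
    -8.2876998125259227e-01, -3.9568947305594188e-01, -3.9568947305594188e-01,
    4.7836902881215021e-01, 8.7815891060406615e-01, 0.0000000000000000e+00,
    -4.7836902881215021e-01, 8.7815891060406615e-01, 0.0000000000000000e+00,
    4.7836902881215021e-01, -8.7815891060406615e-01, 0.0000000000000000e+00,
    -4.7836902881215021e-01, -8.7815891060406615e-01, 0.0000000000000000e+00,
    8.7815891060406615e-01, 4.7836902881215021e-01, 0.0000000000000000e+00,
    -8.7815891060406615e-01, 4.7836902881215021e-01, 0.0000000000000000e+00,
    8.7815891060406615e-01, -4.7836902881215021e-01, 0.0000000000000000e+00,
    -8.7815891060406615e-01, -4.7836902881215021e-01, 0.0000000000000000e+00,
    4.7836902881215021e-01, 0.0000000000000000e+00, 8.7815891060406615e-01,
    -4.7836902881215021e-01, 0.0000000000000000e+00, 8.7815891060406615e-01,
    4.7836902881215021e-01, 0.0000000000000000e+00, -8.7815891060406615e-01,
    -4.7836902881215021e-01, 0.0000000000000000e+00, -8.7815891060406615e-01,
    8.7815891060406615e-01, 0.0000000000000000e+00, 4.7836902881215021e-01,
    -8.7815891060406615e-01, 0.0000000000000000e+00, 4.7836902881215021e-01,
    8.7815891060406615e-01, 0.0000000000000000e+00, -4.7836902881215021e-01,
    -8.7815891060406615e-01, 0.0000000000000000e+00, -4.7836902881215021e-01,
    0.0000000000000000e+00, 4.7836902881215021e-01, 8.7815891060406615e-01,
    0.0000000000000000e+00, -4.7836902881215021e-01, 8.7815891060406615e-01,
    0.0000000000000000e+00, 4.7836902881215021e-01, -8.7815891060406615e-01,
    0.0000000000000000e+00, -4.7836902881215021e-01, -8.7815891060406615e-01,
    0.0000000000000000e+00, 8.7815891060406615e-01, 4.7836902881215021e-01,
    0.0000000000000000e+00, -8.7815891060406615e-01, 4.7836902881215021e-01,
    0.0000000000000000e+00, 8.7815891060406615e-01, -4.7836902881215021e-01,
    0.0000000000000000e+00, -8.7815891060406615e-01, -4.7836902881215021e-01
  ), ncol = 3L, byrow = TRUE),
  w = c(
    3.8282704949371611e-03, 3.8282704949371611e-03, 3.8282704949371611e-03, 3.8282704949371611e-03,
    3.8282704949371611e-03, 3.8282704949371611e-03, 9.7937375124875110e-03, 9.7937375124875110e-03,
    9.7937375124875110e-03, 9.7937375124875110e-03, 9.7937375124875110e-03, 9.7937375124875110e-03,
    9.7937375124875110e-03, 9.7937375124875110e-03, 8.2117372831911097e-03, 8.2117372831911097e-03,
    8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03,
    8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03,
    8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03,
    8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03,
    8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03, 8.2117372831911097e-03,
    8.2117372831911097e-03, 8.2117372831911097e-03, 9.9428148911781013e-03, 9.9428148911781013e-03,
    9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03,
    9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03,
    9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03,
    9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03,
    9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03, 9.9428148911781013e-03,
    9.9428148911781013e-03, 9.9428148911781013e-03, 9.5954713360709605e-03, 9.5954713360709605e-03,
    9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03,
    9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03,
    9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03,
    9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03,
    9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03, 9.5954713360709605e-03,
    9.5954713360709605e-03, 9.5954713360709605e-03, 9.6949963616630268e-03, 9.6949963616630268e-03,
    9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03,
    9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03,
    9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03,
    9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03,
    9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03, 9.6949963616630268e-03,
    9.6949963616630268e-03, 9.6949963616630268e-03
  ))
.lebedev_raw[["194"]] <- list(precision = 23L,
  xyz = matrix(c(
    1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    -1.0000000000000000e+00, 0.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, -1.0000000000000000e+00, 0.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, 1.0000000000000000e+00,
    0.0000000000000000e+00, 0.0000000000000000e+00, -1.0000000000000000e+00,
    0.0000000000000000e+00, 7.0710678118654757e-01, 7.0710678118654757e-01,
    0.0000000000000000e+00, -7.0710678118654757e-01, 7.0710678118654757e-01,
    0.0000000000000000e+00, 7.0710678118654757e-01, -7.0710678118654757e-01,
    0.0000000000000000e+00, -7.0710678118654757e-01, -7.0710678118654757e-01,
    7.0710678118654757e-01, 0.0000000000000000e+00, 7.0710678118654757e-01,
    7.0710678118654757e-01, 0.0000000000000000e+00, -7.0710678118654757e-01,
    -7.0710678118654757e-01, 0.0000000000000000e+00, 7.0710678118654757e-01,
    -7.0710678118654757e-01, 0.0000000000000000e+00, -7.0710678118654757e-01,
    7.0710678118654757e-01, 7.0710678118654757e-01, 0.0000000000000000e+00,
    -7.0710678118654757e-01, 7.0710678118654757e-01, 0.0000000000000000e+00,
    7.0710678118654757e-01, -7.0710678118654757e-01, 0.0000000000000000e+00,
    -7.0710678118654757e-01, -7.0710678118654757e-01, 0.0000000000000000e+00,
    5.7735026918962573e-01, 5.7735026918962573e-01, 5.7735026918962573e-01,
    -5.7735026918962573e-01, 5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, -5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, 5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, -5.7735026918962573e-01, 5.7735026918962573e-01,
    5.7735026918962573e-01, -5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, 5.7735026918962573e-01, -5.7735026918962573e-01,
    -5.7735026918962573e-01, -5.7735026918962573e-01, -5.7735026918962573e-01,
    6.7129734426952259e-01, 6.7129734426952259e-01, 3.1419699418258629e-01,
    -6.7129734426952259e-01, 6.7129734426952259e-01, 3.1419699418258629e-01,
    6.7129734426952259e-01, -6.7129734426952259e-01, 3.1419699418258629e-01,
    6.7129734426952259e-01, 6.7129734426952259e-01, -3.1419699418258629e-01,
    -6.7129734426952259e-01, -6.7129734426952259e-01, 3.1419699418258629e-01,
    -6.7129734426952259e-01, 6.7129734426952259e-01, -3.1419699418258629e-01,
    6.7129734426952259e-01, -6.7129734426952259e-01, -3.1419699418258629e-01,
    -6.7129734426952259e-01, -6.7129734426952259e-01, -3.1419699418258629e-01,
    -6.7129734426952259e-01, 3.1419699418258629e-01, 6.7129734426952259e-01,
    6.7129734426952259e-01, -3.1419699418258629e-01, 6.7129734426952259e-01,
    6.7129734426952259e-01, 3.1419699418258629e-01, -6.7129734426952259e-01,
    -6.7129734426952259e-01, -3.1419699418258629e-01, 6.7129734426952259e-01,
    -6.7129734426952259e-01, 3.1419699418258629e-01, -6.7129734426952259e-01,
    6.7129734426952259e-01, -3.1419699418258629e-01, -6.7129734426952259e-01,
    -6.7129734426952259e-01, -3.1419699418258629e-01, -6.7129734426952259e-01,
    6.7129734426952259e-01, 3.1419699418258629e-01, 6.7129734426952259e-01,
    3.1419699418258629e-01, 6.7129734426952259e-01, 6.7129734426952259e-01,
    -3.1419699418258629e-01, 6.7129734426952259e-01, 6.7129734426952259e-01,
    3.1419699418258629e-01, -6.7129734426952259e-01, 6.7129734426952259e-01,
    3.1419699418258629e-01, 6.7129734426952259e-01, -6.7129734426952259e-01,
    -3.1419699418258629e-01, -6.7129734426952259e-01, 6.7129734426952259e-01,
    -3.1419699418258629e-01, 6.7129734426952259e-01, -6.7129734426952259e-01,
    3.1419699418258629e-01, -6.7129734426952259e-01, -6.7129734426952259e-01,
    -3.1419699418258629e-01, -6.7129734426952259e-01, -6.7129734426952259e-01,
    2.8924656275754390e-01, 2.8924656275754390e-01, 9.1250909686747372e-01,
    -2.8924656275754390e-01, 2.8924656275754390e-01, 9.1250909686747372e-01,
    2.8924656275754390e-01, -2.8924656275754390e-01, 9.1250909686747372e-01,
    2.8924656275754390e-01, 2.8924656275754390e-01, -9.1250909686747372e-01,
    -2.8924656275754390e-01, -2.8924656275754390e-01, 9.1250909686747372e-01,
    -2.8924656275754390e-01, 2.8924656275754390e-01, -9.1250909686747372e-01,
    2.8924656275754390e-01, -2.8924656275754390e-01, -9.1250909686747372e-01,
    -2.8924656275754390e-01, -2.8924656275754390e-01, -9.1250909686747372e-01,
    -2.8924656275754390e-01, 9.1250909686747372e-01, 2.8924656275754390e-01,
    2.8924656275754390e-01, -9.1250909686747372e-01, 2.8924656275754390e-01,
    2.8924656275754390e-01, 9.1250909686747372e-01, -2.8924656275754390e-01,
    -2.8924656275754390e-01, -9.1250909686747372e-01, 2.8924656275754390e-01,
    -2.8924656275754390e-01, 9.1250909686747372e-01, -2.8924656275754390e-01,
    2.8924656275754390e-01, -9.1250909686747372e-01, -2.8924656275754390e-01,
    -2.8924656275754390e-01, -9.1250909686747372e-01, -2.8924656275754390e-01,
    2.8924656275754390e-01, 9.1250909686747372e-01, 2.8924656275754390e-01,
    9.1250909686747372e-01, 2.8924656275754390e-01, 2.8924656275754390e-01,
    -9.1250909686747372e-01, 2.8924656275754390e-01, 2.8924656275754390e-01,
    9.1250909686747372e-01, -2.8924656275754390e-01, 2.8924656275754390e-01,
    9.1250909686747372e-01, 2.8924656275754390e-01, -2.8924656275754390e-01,
    -9.1250909686747372e-01, -2.8924656275754390e-01, 2.8924656275754390e-01,
    -9.1250909686747372e-01, 2.8924656275754390e-01, -2.8924656275754390e-01,
    9.1250909686747372e-01, -2.8924656275754390e-01, -2.8924656275754390e-01,
    -9.1250909686747372e-01, -2.8924656275754390e-01, -2.8924656275754390e-01,
    4.4469331787174371e-01, 4.4469331787174371e-01, 7.7749321931476711e-01,
    -4.4469331787174371e-01, 4.4469331787174371e-01, 7.7749321931476711e-01,
    4.4469331787174371e-01, -4.4469331787174371e-01, 7.7749321931476711e-01,
    4.4469331787174371e-01, 4.4469331787174371e-01, -7.7749321931476711e-01,
    -4.4469331787174371e-01, -4.4469331787174371e-01, 7.7749321931476711e-01,
    -4.4469331787174371e-01, 4.4469331787174371e-01, -7.7749321931476711e-01,
    4.4469331787174371e-01, -4.4469331787174371e-01, -7.7749321931476711e-01,
    -4.4469331787174371e-01, -4.4469331787174371e-01, -7.7749321931476711e-01,
    -4.4469331787174371e-01, 7.7749321931476711e-01, 4.4469331787174371e-01,
    4.4469331787174371e-01, -7.7749321931476711e-01, 4.4469331787174371e-01,
    4.4469331787174371e-01, 7.7749321931476711e-01, -4.4469331787174371e-01,
    -4.4469331787174371e-01, -7.7749321931476711e-01, 4.4469331787174371e-01,
    -4.4469331787174371e-01, 7.7749321931476711e-01, -4.4469331787174371e-01,
    4.4469331787174371e-01, -7.7749321931476711e-01, -4.4469331787174371e-01,
    -4.4469331787174371e-01, -7.7749321931476711e-01, -4.4469331787174371e-01,
    4.4469331787174371e-01, 7.7749321931476711e-01, 4.4469331787174371e-01,
    7.7749321931476711e-01, 4.4469331787174371e-01, 4.4469331787174371e-01,
    -7.7749321931476711e-01, 4.4469331787174371e-01, 4.4469331787174371e-01,
    7.7749321931476711e-01, -4.4469331787174371e-01, 4.4469331787174371e-01,
    7.7749321931476711e-01, 4.4469331787174371e-01, -4.4469331787174371e-01,
    -7.7749321931476711e-01, -4.4469331787174371e-01, 4.4469331787174371e-01,
    -7.7749321931476711e-01, 4.4469331787174371e-01, -4.4469331787174371e-01,
    7.7749321931476711e-01, -4.4469331787174371e-01, -4.4469331787174371e-01,
    -7.7749321931476711e-01, -4.4469331787174371e-01, -4.4469331787174371e-01,
    1.2993354476500671e-01, 1.2993354476500671e-01, 9.8297230270725322e-01,
    -1.2993354476500671e-01, 1.2993354476500671e-01, 9.8297230270725322e-01,
    1.2993354476500671e-01, -1.2993354476500671e-01, 9.8297230270725322e-01,
    1.2993354476500671e-01, 1.2993354476500671e-01, -9.8297230270725322e-01,
    -1.2993354476500671e-01, -1.2993354476500671e-01, 9.8297230270725322e-01,
    -1.2993354476500671e-01, 1.2993354476500671e-01, -9.8297230270725322e-01,
    1.2993354476500671e-01, -1.2993354476500671e-01, -9.8297230270725322e-01,
    -1.2993354476500671e-01, -1.2993354476500671e-01, -9.8297230270725322e-01,
    -1.2993354476500671e-01, 9.8297230270725322e-01, 1.2993354476500671e-01,
    1.2993354476500671e-01, -9.8297230270725322e-01, 1.2993354476500671e-01,
    1.2993354476500671e-01, 9.8297230270725322e-01, -1.2993354476500671e-01,
    -1.2993354476500671e-01, -9.8297230270725322e-01, 1.2993354476500671e-01,
    -1.2993354476500671e-01, 9.8297230270725322e-01, -1.2993354476500671e-01,
    1.2993354476500671e-01, -9.8297230270725322e-01, -1.2993354476500671e-01,
    -1.2993354476500671e-01, -9.8297230270725322e-01, -1.2993354476500671e-01,
    1.2993354476500671e-01, 9.8297230270725322e-01, 1.2993354476500671e-01,
    9.8297230270725322e-01, 1.2993354476500671e-01, 1.2993354476500671e-01,
    -9.8297230270725322e-01, 1.2993354476500671e-01, 1.2993354476500671e-01,
    9.8297230270725322e-01, -1.2993354476500671e-01, 1.2993354476500671e-01,
    9.8297230270725322e-01, 1.2993354476500671e-01, -1.2993354476500671e-01,
    -9.8297230270725322e-01, -1.2993354476500671e-01, 1.2993354476500671e-01,
    -9.8297230270725322e-01, 1.2993354476500671e-01, -1.2993354476500671e-01,
    9.8297230270725322e-01, -1.2993354476500671e-01, -1.2993354476500671e-01,
    -9.8297230270725322e-01, -1.2993354476500671e-01, -1.2993354476500671e-01,
    3.4577021976112832e-01, 9.3831921813759156e-01, 0.0000000000000000e+00,
    -3.4577021976112832e-01, 9.3831921813759156e-01, 0.0000000000000000e+00,
    3.4577021976112832e-01, -9.3831921813759156e-01, 0.0000000000000000e+00,
    -3.4577021976112832e-01, -9.3831921813759156e-01, 0.0000000000000000e+00,
    9.3831921813759156e-01, 3.4577021976112832e-01, 0.0000000000000000e+00,
    -9.3831921813759156e-01, 3.4577021976112832e-01, 0.0000000000000000e+00,
    9.3831921813759156e-01, -3.4577021976112832e-01, 0.0000000000000000e+00,
    -9.3831921813759156e-01, -3.4577021976112832e-01, 0.0000000000000000e+00,
    3.4577021976112832e-01, 0.0000000000000000e+00, 9.3831921813759156e-01,
    -3.4577021976112832e-01, 0.0000000000000000e+00, 9.3831921813759156e-01,
    3.4577021976112832e-01, 0.0000000000000000e+00, -9.3831921813759156e-01,
    -3.4577021976112832e-01, 0.0000000000000000e+00, -9.3831921813759156e-01,
    9.3831921813759156e-01, 0.0000000000000000e+00, 3.4577021976112832e-01,
    -9.3831921813759156e-01, 0.0000000000000000e+00, 3.4577021976112832e-01,
    9.3831921813759156e-01, 0.0000000000000000e+00, -3.4577021976112832e-01,
    -9.3831921813759156e-01, 0.0000000000000000e+00, -3.4577021976112832e-01,
    0.0000000000000000e+00, 3.4577021976112832e-01, 9.3831921813759156e-01,
    0.0000000000000000e+00, -3.4577021976112832e-01, 9.3831921813759156e-01,
    0.0000000000000000e+00, 3.4577021976112832e-01, -9.3831921813759156e-01,
    0.0000000000000000e+00, -3.4577021976112832e-01, -9.3831921813759156e-01,
    0.0000000000000000e+00, 9.3831921813759156e-01, 3.4577021976112832e-01,
    0.0000000000000000e+00, -9.3831921813759156e-01, 3.4577021976112832e-01,
    0.0000000000000000e+00, 9.3831921813759156e-01, -3.4577021976112832e-01,
    0.0000000000000000e+00, -9.3831921813759156e-01, -3.4577021976112832e-01,
    1.5904171053835300e-01, 8.3603601548245887e-01, 5.2511857244364202e-01,
    -1.5904171053835300e-01, 8.3603601548245887e-01, 5.2511857244364202e-01,
    1.5904171053835300e-01, -8.3603601548245887e-01, 5.2511857244364202e-01,
    1.5904171053835300e-01, 8.3603601548245887e-01, -5.2511857244364202e-01,
    -1.5904171053835300e-01, -8.3603601548245887e-01, 5.2511857244364202e-01,
    1.5904171053835300e-01, -8.3603601548245887e-01, -5.2511857244364202e-01,
    -1.5904171053835300e-01, 8.3603601548245887e-01, -5.2511857244364202e-01,
    -1.5904171053835300e-01, -8.3603601548245887e-01, -5.2511857244364202e-01,
    8.3603601548245887e-01, 1.5904171053835300e-01, 5.2511857244364202e-01,
    -8.3603601548245887e-01, 1.5904171053835300e-01, 5.2511857244364202e-01,
    8.3603601548245887e-01, -1.5904171053835300e-01, 5.2511857244364202e-01,
    8.3603601548245887e-01, 1.5904171053835300e-01, -5.2511857244364202e-01,
    -8.3603601548245887e-01, -1.5904171053835300e-01, 5.2511857244364202e-01,
    8.3603601548245887e-01, -1.5904171053835300e-01, -5.2511857244364202e-01,
    -8.3603601548245887e-01, 1.5904171053835300e-01, -5.2511857244364202e-01,
    -8.3603601548245887e-01, -1.5904171053835300e-01, -5.2511857244364202e-01,
    5.2511857244364202e-01, 1.5904171053835300e-01, 8.3603601548245887e-01,
    -5.2511857244364202e-01, 1.5904171053835300e-01, 8.3603601548245887e-01,
    5.2511857244364202e-01, -1.5904171053835300e-01, 8.3603601548245887e-01,
    5.2511857244364202e-01, 1.5904171053835300e-01, -8.3603601548245887e-01,
    -5.2511857244364202e-01, -1.5904171053835300e-01, 8.3603601548245887e-01,
    5.2511857244364202e-01, -1.5904171053835300e-01, -8.3603601548245887e-01,
    -5.2511857244364202e-01, 1.5904171053835300e-01, -8.3603601548245887e-01,
    -5.2511857244364202e-01, -1.5904171053835300e-01, -8.3603601548245887e-01,
    5.2511857244364202e-01, 8.3603601548245887e-01, 1.5904171053835300e-01,
    -5.2511857244364202e-01, 8.3603601548245887e-01, 1.5904171053835300e-01,
    5.2511857244364202e-01, -8.3603601548245887e-01, 1.5904171053835300e-01,
    5.2511857244364202e-01, 8.3603601548245887e-01, -1.5904171053835300e-01,
    -5.2511857244364202e-01, -8.3603601548245887e-01, 1.5904171053835300e-01,
    5.2511857244364202e-01, -8.3603601548245887e-01, -1.5904171053835300e-01,
    -5.2511857244364202e-01, 8.3603601548245887e-01, -1.5904171053835300e-01,
    -5.2511857244364202e-01, -8.3603601548245887e-01, -1.5904171053835300e-01,
    1.5904171053835300e-01, 5.2511857244364202e-01, 8.3603601548245887e-01,
    -1.5904171053835300e-01, 5.2511857244364202e-01, 8.3603601548245887e-01,
    1.5904171053835300e-01, -5.2511857244364202e-01, 8.3603601548245887e-01,
    1.5904171053835300e-01, 5.2511857244364202e-01, -8.3603601548245887e-01,
    -1.5904171053835300e-01, -5.2511857244364202e-01, 8.3603601548245887e-01,
    1.5904171053835300e-01, -5.2511857244364202e-01, -8.3603601548245887e-01,
    -1.5904171053835300e-01, 5.2511857244364202e-01, -8.3603601548245887e-01,
    -1.5904171053835300e-01, -5.2511857244364202e-01, -8.3603601548245887e-01,
    8.3603601548245887e-01, 5.2511857244364202e-01, 1.5904171053835300e-01,
    -8.3603601548245887e-01, 5.2511857244364202e-01, 1.5904171053835300e-01,
    8.3603601548245887e-01, -5.2511857244364202e-01, 1.5904171053835300e-01,
    8.3603601548245887e-01, 5.2511857244364202e-01, -1.5904171053835300e-01,
    -8.3603601548245887e-01, -5.2511857244364202e-01, 1.5904171053835300e-01,
    8.3603601548245887e-01, -5.2511857244364202e-01, -1.5904171053835300e-01,
    -8.3603601548245887e-01, 5.2511857244364202e-01, -1.5904171053835300e-01,
    -8.3603601548245887e-01, -5.2511857244364202e-01, -1.5904171053835300e-01
  ), ncol = 3L, byrow = TRUE),
  w = c(
    1.7823404472446110e-03, 1.7823404472446110e-03, 1.7823404472446110e-03, 1.7823404472446110e-03,
    1.7823404472446110e-03, 1.7823404472446110e-03, 5.7169059499771017e-03, 5.7169059499771017e-03,
    5.7169059499771017e-03, 5.7169059499771017e-03, 5.7169059499771017e-03, 5.7169059499771017e-03,
    5.7169059499771017e-03, 5.7169059499771017e-03, 5.7169059499771017e-03, 5.7169059499771017e-03,
    5.7169059499771017e-03, 5.7169059499771017e-03, 5.5733831788487374e-03, 5.5733831788487374e-03,
    5.5733831788487374e-03, 5.5733831788487374e-03, 5.5733831788487374e-03, 5.5733831788487374e-03,
    5.5733831788487374e-03, 5.5733831788487374e-03, 5.6087040825879972e-03, 5.6087040825879972e-03,
    5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03,
    5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03,
    5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03,
    5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03,
    5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03, 5.6087040825879972e-03,
    5.6087040825879972e-03, 5.6087040825879972e-03, 5.1582377118053833e-03, 5.1582377118053833e-03,
    5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03,
    5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03,
    5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03,
    5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03,
    5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03, 5.1582377118053833e-03,
    5.1582377118053833e-03, 5.1582377118053833e-03, 5.5187714672736143e-03, 5.5187714672736143e-03,
    5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03,
    5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03,
    5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03,
    5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03,
    5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03, 5.5187714672736143e-03,
    5.5187714672736143e-03, 5.5187714672736143e-03, 4.1067770281693937e-03, 4.1067770281693937e-03,
    4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03,
    4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03,
    4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03,
    4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03,
    4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03, 4.1067770281693937e-03,
    4.1067770281693937e-03, 4.1067770281693937e-03, 5.0518460646148079e-03, 5.0518460646148079e-03,
    5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03,
    5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03,
    5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03,
    5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03,
    5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03, 5.0518460646148079e-03,
    5.0518460646148079e-03, 5.0518460646148079e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03, 5.5302489162330944e-03,
    5.5302489162330944e-03, 5.5302489162330944e-03
  ))
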