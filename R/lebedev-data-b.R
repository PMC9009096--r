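# Lebedev-Laikov quadrature nodes on the unit sphere (octahedral symmetry),
# normalized so that weights sum to 1.  Nodes of algebraic precision p
# integrate spherical harmonics exactly up to degree p.

.lebedev_raw[["302"]] <- list(precision = 29L,
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
    3.5156403455701052e-01, 3.5156403455701052e-01, 8.6764362454408339e-01,
    -3.5156403455701052e-01, 3.5156403455701052e-01, 8.6764362454408339e-01,
    3.5156403455701052e-01, -3.5156403455701052e-01, 8.6764362454408339e-01,
    3.5156403455701052e-01, 3.5156403455701052e-01, -8.6764362454408339e-01,
    -3.5156403455701052e-01, -3.5156403455701052e-01, 8.6764362454408339e-01,
    -3.5156403455701052e-01, 3.5156403455701052e-01, -8.6764362454408339e-01,
    3.5156403455701052e-01, -3.5156403455701052e-01, -8.6764362454408339e-01,
    -3.5156403455701052e-01, -3.5156403455701052e-01, -8.6764362454408339e-01,
    -3.5156403455701052e-01, 8.6764362454408339e-01, 3.5156403455701052e-01,
    3.5156403455701052e-01, -8.6764362454408339e-01, 3.5156403455701052e-01,
    3.5156403455701052e-01, 8.6764362454408339e-01, -3.5156403455701052e-01,
    -3.5156403455701052e-01, -8.6764362454408339e-01, 3.5156403455701052e-01,
    -3.5156403455701052e-01, 8.6764362454408339e-01, -3.5156403455701052e-01,
    3.5156403455701052e-01, -8.6764362454408339e-01, -3.5156403455701052e-01,
    -3.5156403455701052e-01, -8.6764362454408339e-01, -3.5156403455701052e-01,
    3.5156403455701052e-01, 8.6764362454408339e-01, 3.5156403455701052e-01,
    8.6764362454408339e-01, 3.5156403455701052e-01, 3.5156403455701052e-01,
    -8.6764362454408339e-01, 3.5156403455701052e-01, 3.5156403455701052e-01,
    8.6764362454408339e-01, -3.5156403455701052e-01, 3.5156403455701052e-01,
    8.6764362454408339e-01, 3.5156403455701052e-01, -3.5156403455701052e-01,
    -8.6764362454408339e-01, -3.5156403455701052e-01, 3.5156403455701052e-01,
    -8.6764362454408339e-01, 3.5156403455701052e-01, -3.5156403455701052e-01,
    8.6764362454408339e-01, -3.5156403455701052e-01, -3.5156403455701052e-01,
    -8.6764362454408339e-01, -3.5156403455701052e-01, -3.5156403455701052e-01,
    6.5663294102196124e-01, 6.5663294102196124e-01, 3.7103417838482095e-01,
    -6.5663294102196124e-01, 6.5663294102196124e-01, 3.7103417838482095e-01,
    6.5663294102196124e-01, -6.5663294102196124e-01, 3.7103417838482095e-01,
    6.5663294102196124e-01, 6.5663294102196124e-01, -3.7103417838482095e-01,
    -6.5663294102196124e-01, -6.5663294102196124e-01, 3.7103417838482095e-01,
    -6.5663294102196124e-01, 6.5663294102196124e-01, -3.7103417838482095e-01,
    6.5663294102196124e-01, -6.5663294102196124e-01, -3.7103417838482095e-01,
    -6.5663294102196124e-01, -6.5663294102196124e-01, -3.7103417838482095e-01,
    -6.5663294102196124e-01, 3.7103417838482095e-01, 6.5663294102196124e-01,
    6.5663294102196124e-01, -3.7103417838482095e-01, 6.5663294102196124e-01,
    6.5663294102196124e-01, 3.7103417838482095e-01, -6.5663294102196124e-01,
    -6.5663294102196124e-01, -3.7103417838482095e-01, 6.5663294102196124e-01,
    -6.5663294102196124e-01, 3.7103417838482095e-01, -6.5663294102196124e-01,
    6.5663294102196124e-01, -3.7103417838482095e-01, -6.5663294102196124e-01,
    -6.5663294102196124e-01, -3.7103417838482095e-01, -6.5663294102196124e-01,
    6.5663294102196124e-01, 3.7103417838482095e-01, 6.5663294102196124e-01,
    3.7103417838482095e-01, 6.5663294102196124e-01, 6.5663294102196124e-01,
    -3.7103417838482095e-01, 6.5663294102196124e-01, 6.5663294102196124e-01,
    3.7103417838482095e-01, -6.5663294102196124e-01, 6.5663294102196124e-01,
    3.7103417838482095e-01, 6.5663294102196124e-01, -6.5663294102196124e-01,
    -3.7103417838482095e-01, -6.5663294102196124e-01, 6.5663294102196124e-01,
    -3.7103417838482095e-01, 6.5663294102196124e-01, -6.5663294102196124e-01,
    3.7103417838482095e-01, -6.5663294102196124e-01, -6.5663294102196124e-01,
    -3.7103417838482095e-01, -6.5663294102196124e-01, -6.5663294102196124e-01,
    4.7290541325810048e-01, 4.7290541325810048e-01, 7.4345204298755574e-01,
    -4.7290541325810048e-01, 4.7290541325810048e-01, 7.4345204298755574e-01,
    4.7290541325810048e-01, -4.7290541325810048e-01, 7.4345204298755574e-01,
    4.7290541325810048e-01, 4.7290541325810048e-01, -7.4345204298755574e-01,
    -4.7290541325810048e-01, -4.7290541325810048e-01, 7.4345204298755574e-01,
    -4.7290541325810048e-01, 4.7290541325810048e-01, -7.4345204298755574e-01,
    4.7290541325810048e-01, -4.7290541325810048e-01, -7.4345204298755574e-01,
    -4.7290541325810048e-01, -4.7290541325810048e-01, -7.4345204298755574e-01,
    -4.7290541325810048e-01, 7.4345204298755574e-01, 4.7290541325810048e-01,
    4.7290541325810048e-01, -7.4345204298755574e-01, 4.7290541325810048e-01,
    4.7290541325810048e-01, 7.4345204298755574e-01, -4.7290541325810048e-01,
    -4.7290541325810048e-01, -7.4345204298755574e-01, 4.7290541325810048e-01,
    -4.7290541325810048e-01, 7.4345204298755574e-01, -4.7290541325810048e-01,
    4.7290541325810048e-01, -7.4345204298755574e-01, -4.7290541325810048e-01,
    -4.7290541325810048e-01, -7.4345204298755574e-01, -4.7290541325810048e-01,
    4.7290541325810048e-01, 7.4345204298755574e-01, 4.7290541325810048e-01,
    7.4345204298755574e-01, 4.7290541325810048e-01, 4.7290541325810048e-01,
    -7.4345204298755574e-01, 4.7290541325810048e-01, 4.7290541325810048e-01,
    7.4345204298755574e-01, -4.7290541325810048e-01, 4.7290541325810048e-01,
    7.4345204298755574e-01, 4.7290541325810048e-01, -4.7290541325810048e-01,
    -7.4345204298755574e-01, -4.7290541325810048e-01, 4.7290541325810048e-01,
    -7.4345204298755574e-01, 4.7290541325810048e-01, -4.7290541325810048e-01,
    7.4345204298755574e-01, -4.7290541325810048e-01, -4.7290541325810048e-01,
    -7.4345204298755574e-01, -4.7290541325810048e-01, -4.7290541325810048e-01,
    9.6183085226147838e-02, 9.6183085226147838e-02, 9.9070562137940810e-01,
    -9.6183085226147838e-02, 9.6183085226147838e-02, 9.9070562137940810e-01,
    9.6183085226147838e-02, -9.6183085226147838e-02, 9.9070562137940810e-01,
    9.6183085226147838e-02, 9.6183085226147838e-02, -9.9070562137940810e-01,
    -9.6183085226147838e-02, -9.6183085226147838e-02, 9.9070562137940810e-01,
    -9.6183085226147838e-02, 9.6183085226147838e-02, -9.9070562137940810e-01,
    9.6183085226147838e-02, -9.6183085226147838e-02, -9.9070562137940810e-01,
    -9.6183085226147838e-02, -9.6183085226147838e-02, -9.9070562137940810e-01,
    -9.6183085226147838e-02, 9.9070562137940810e-01, 9.6183085226147838e-02,
    9.6183085226147838e-02, -9.9070562137940810e-01, 9.6183085226147838e-02,
    9.6183085226147838e-02, 9.9070562137940810e-01, -9.6183085226147838e-02,
    -9.6183085226147838e-02, -9.9070562137940810e-01, 9.6183085226147838e-02,
    -9.6183085226147838e-02, 9.9070562137940810e-01, -9.6183085226147838e-02,
    9.6183085226147838e-02, -9.9070562137940810e-01, -9.6183085226147838e-02,
    -9.6183085226147838e-02, -9.9070562137940810e-01, -9.6183085226147838e-02,
    9.6183085226147838e-02, 9.9070562137940810e-01, 9.6183085226147838e-02,
    9.9070562137940810e-01, 9.6183085226147838e-02, 9.6183085226147838e-02,
    -9.9070562137940810e-01, 9.6183085226147838e-02, 9.6183085226147838e-02,
    9.9070562137940810e-01, -9.6183085226147838e-02, 9.6183085226147838e-02,
    9.9070562137940810e-01, 9.6183085226147838e-02, -9.6183085226147838e-02,
    -9.9070562137940810e-01, -9.6183085226147838e-02, 9.6183085226147838e-02,
    -9.9070562137940810e-01, 9.6183085226147838e-02, -9.6183085226147838e-02,
    9.9070562137940810e-01, -9.6183085226147838e-02, -9.6183085226147838e-02,
    -9.9070562137940810e-01, -9.6183085226147838e-02, -9.6183085226147838e-02,
    2.2196452362941779e-01, 2.2196452362941779e-01, 9.4945431722644313e-01,
    -2.2196452362941779e-01, 2.2196452362941779e-01, 9.4945431722644313e-01,
    2.2196452362941779e-01, -2.2196452362941779e-01, 9.4945431722644313e-01,
    2.2196452362941779e-01, 2.2196452362941779e-01, -9.4945431722644313e-01,
    -2.2196452362941779e-01, -2.2196452362941779e-01, 9.4945431722644313e-01,
    -2.2196452362941779e-01, 2.2196452362941779e-01, -9.4945431722644313e-01,
    2.2196452362941779e-01, -2.2196452362941779e-01, -9.4945431722644313e-01,
    -2.2196452362941779e-01, -2.2196452362941779e-01, -9.4945431722644313e-01,
    -2.2196452362941779e-01, 9.4945431722644313e-01, 2.2196452362941779e-01,
    2.2196452362941779e-01, -9.4945431722644313e-01, 2.2196452362941779e-01,
    2.2196452362941779e-01, 9.4945431722644313e-01, -2.2196452362941779e-01,
    -2.2196452362941779e-01, -9.4945431722644313e-01, 2.2196452362941779e-01,
    -2.2196452362941779e-01, 9.4945431722644313e-01, -2.2196452362941779e-01,
    2.2196452362941779e-01, -9.4945431722644313e-01, -2.2196452362941779e-01,
    -2.2196452362941779e-01, -9.4945431722644313e-01, -2.2196452362941779e-01,
    2.2196452362941779e-01, 9.4945431722644313e-01, 2.2196452362941779e-01,
    9.4945431722644313e-01, 2.2196452362941779e-01, 2.2196452362941779e-01,
    -9.4945431722644313e-01, 2.2196452362941779e-01, 2.2196452362941779e-01,
    9.4945431722644313e-01, -2.2196452362941779e-01, 2.2196452362941779e-01,
    9.4945431722644313e-01, 2.2196452362941779e-01, -2.2196452362941779e-01,
    -9.4945431722644313e-01, -2.2196452362941779e-01, 2.2196452362941779e-01,
    -9.4945431722644313e-01, 2.2196452362941779e-01, -2.2196452362941779e-01,
    9.4945431722644313e-01, -2.2196452362941779e-01, -2.2196452362941779e-01,
    -9.4945431722644313e-01, -2.2196452362941779e-01, -2.2196452362941779e-01,
    7.0117664160895454e-01, 7.0117664160895454e-01, 1.2923867271051442e-01,
    -7.0117664160895454e-01, 7.0117664160895454e-01, 1.2923867271051442e-01,
    7.0117664160895454e-01, -7.0117664160895454e-01, 1.2923867271051442e-01,
    7.0117664160895454e-01, 7.0117664160895454e-01, -1.2923867271051442e-01,
    -7.0117664160895454e-01, -7.0117664160895454e-01, 1.2923867271051442e-01,
    -7.0117664160895454e-01, 7.0117664160895454e-01, -1.2923867271051442e-01,
    7.0117664160895454e-01, -7.0117664160895454e-01, -1.2923867271051442e-01,
    -7.0117664160895454e-01, -7.0117664160895454e-01, -1.2923867271051442e-01,
    -7.0117664160895454e-01, 1.2923867271051442e-01, 7.0117664160895454e-01,
    7.0117664160895454e-01, -1.2923867271051442e-01, 7.0117664160895454e-01,
    7.0117664160895454e-01, 1.2923867271051442e-01, -7.0117664160895454e-01,
    -7.0117664160895454e-01, -1.2923867271051442e-01, 7.0117664160895454e-01,
    -7.0117664160895454e-01, 1.2923867271051442e-01, -7.0117664160895454e-01,
    7.0117664160895454e-01, -1.2923867271051442e-01, -7.0117664160895454e-01,
    -7.0117664160895454e-01, -1.2923867271051442e-01, -7.0117664160895454e-01,
    7.0117664160895454e-01, 1.2923867271051442e-01, 7.0117664160895454e-01,
    1.2923867271051442e-01, 7.0117664160895454e-01, 7.0117664160895454e-01,
    -1.2923867271051442e-01, 7.0117664160895454e-01, 7.0117664160895454e-01,
    1.2923867271051442e-01, -7.0117664160895454e-01, 7.0117664160895454e-01,
    1.2923867271051442e-01, 7.0117664160895454e-01, -7.0117664160895454e-01,
    -1.2923867271051442e-01, -7.0117664160895454e-01, 7.0117664160895454e-01,
    -1.2923867271051442e-01, 7.0117664160895454e-01, -7.0117664160895454e-01,
    1.2923867271051442e-01, -7.0117664160895454e-01, -7.0117664160895454e-01,
    -1.2923867271051442e-01, -7.0117664160895454e-01, -7.0117664160895454e-01,
    2.6441528870606629e-01, 9.6440891487920599e-01, 0.0000000000000000e+00,
    -2.6441528870606629e-01, 9.6440891487920599e-01, 0.0000000000000000e+00,
    2.6441528870606629e-01, -9.6440891487920599e-01, 0.0000000000000000e+00,
    -2.6441528870606629e-01, -9.6440891487920599e-01, 0.0000000000000000e+00,
    9.6440891487920599e-01, 2.6441528870606629e-01, 0.0000000000000000e+00,
    -9.6440891487920599e-01, 2.6441528870606629e-01, 0.0000000000000000e+00,
    9.6440891487920599e-01, -2.6441528870606629e-01, 0.0000000000000000e+00,
    -9.6440891487920599e-01, -2.6441528870606629e-01, 0.0000000000000000e+00,
    2.6441528870606629e-01, 0.0000000000000000e+00, 9.6440891487920599e-01,
    -2.6441528870606629e-01, 0.0000000000000000e+00, 9.6440891487920599e-01,
    2.6441528870606629e-01, 0.0000000000000000e+00, -9.6440891487920599e-01,
    -2.6441528870606629e-01, 0.0000000000000000e+00, -9.6440891487920599e-01,
    9.6440891487920599e-01, 0.0000000000000000e+00, 2.6441528870606629e-01,
    -9.6440891487920599e-01, 0.0000000000000000e+00, 2.6441528870606629e-01,
    9.6440891487920599e-01, 0.0000000000000000e+00, -2.6441528870606629e-01,
    -9.6440891487920599e-01, 0.0000000000000000e+00, -2.6441528870606629e-01,
    0.0000000000000000e+00, 2.6441528870606629e-01, 9.6440891487920599e-01,
    0.0000000000000000e+00, -2.6441528870606629e-01, 9.6440891487920599e-01,
    0.0000000000000000e+00, 2.6441528870606629e-01, -9.6440891487920599e-01,
    0.0000000000000000e+00, -2.6441528870606629e-01, -9.6440891487920599e-01,
    0.0000000000000000e+00, 9.6440891487920599e-01, 2.6441528870606629e-01,
    0.0000000000000000e+00, -9.6440891487920599e-01, 2.6441528870606629e-01,
    0.0000000000000000e+00, 9.6440891487920599e-01, -2.6441528870606629e-01,
    0.0000000000000000e+00, -9.6440891487920599e-01, -2.6441528870606629e-01,
    5.7189558918789607e-01, 8.2032641982775933e-01, 0.0000000000000000e+00,
    -5.7189558918789607e-01, 8.2032641982775933e-01, 0.0000000000000000e+00,
    5.7189558918789607e-01, -8.2032641982775933e-01, 0.0000000000000000e+00,
    -5.7189558918789607e-01, -8.2032641982775933e-01, 0.0000000000000000e+00,
    8.2032641982775933e-01, 5.7189558918789607e-01, 0.0000000000000000e+00,
    -8.2032641982775933e-01, 5.7189558918789607e-01, 0.0000000000000000e+00,
    8.2032641982775933e-01, -5.7189558918789607e-01, 0.0000000000000000e+00,
    -8.2032641982775933e-01, -5.7189558918789607e-01, 0.0000000000000000e+00,
    5.7189558918789607e-01, 0.0000000000000000e+00, 8.2032641982775933e-01,
    -5.7189558918789607e-01, 0.0000000000000000e+00, 8.2032641982775933e-01,
    5.7189558918789607e-01, 0.0000000000000000e+00, -8.2032641982775933e-01,
    -5.7189558918789607e-01, 0.0000000000000000e+00, -8.2032641982775933e-01,
    8.2032641982775933e-01, 0.0000000000000000e+00, 5.7189558918789607e-01,
    -8.2032641982775933e-01, 0.0000000000000000e+00, 5.7189558918789607e-01,
    8.2032641982775933e-01, 0.0000000000000000e+00, -5.7189558918789607e-01,
    -8.2032641982775933e-01, 0.0000000000000000e+00, -5.7189558918789607e-01,
    0.0000000000000000e+00, 5.7189558918789607e-01, 8.2032641982775933e-01,
    0.0000000000000000e+00, -5.7189558918789607e-01, 8.2032641982775933e-01,
    0.0000000000000000e+00, 5.7189558918789607e-01, -8.2032641982775933e-01,
    0.0000000000000000e+00, -5.7189558918789607e-01, -8.2032641982775933e-01,
    0.0000000000000000e+00, 8.2032641982775933e-01, 5.7189558918789607e-01,
    0.0000000000000000e+00, -8.2032641982775933e-01, 5.7189558918789607e-01,
    0.0000000000000000e+00, 8.2032641982775933e-01, -5.7189558918789607e-01,
    0.0000000000000000e+00, -8.2032641982775933e-01, -5.7189558918789607e-01,
    2.5100347517704652e-01, 8.0007274940739515e-01, 5.4486773725807736e-01,
    -2.5100347517704652e-01, 8.0007274940739515e-01, 5.4486773725807736e-01,
    2.5100347517704652e-01, -8.0007274940739515e-01, 5.4486773725807736e-01,
    2.5100347517704652e-01, 8.0007274940739515e-01, -5.4486773725807736e-01,
    -2.5100347517704652e-01, -8.0007274940739515e-01, 5.4486773725807736e-01,
    2.5100347517704652e-01, -8.0007274940739515e-01, -5.4486773725807736e-01,
    -2.5100347517704652e-01, 8.0007274940739515e-01, -5.4486773725807736e-01,
    -2.5100347517704652e-01, -8.0007274940739515e-01, -5.4486773725807736e-01,
    8.0007274940739515e-01, 2.5100347517704652e-01, 5.4486773725807736e-01,
    -8.0007274940739515e-01, 2.5100347517704652e-01, 5.4486773725807736e-01,
    8.0007274940739515e-01, -2.5100347517704652e-01, 5.4486773725807736e-01,
    8.0007274940739515e-01, 2.5100347517704652e-01, -5.4486773725807736e-01,
    -8.0007274940739515e-01, -2.5100347517704652e-01, 5.4486773725807736e-01,
    8.0007274940739515e-01, -2.5100347517704652e-01, -5.4486773725807736e-01,
    -8.0007274940739515e-01, 2.5100347517704652e-01, -5.4486773725807736e-01,
    -8.0007274940739515e-01, -2.5100347517704652e-01, -5.4486773725807736e-01,
    5.4486773725807736e-01, 2.5100347517704652e-01, 8.0007274940739515e-01,
    -5.4486773725807736e-01, 2.5100347517704652e-01, 8.0007274940739515e-01,
    5.4486773725807736e-01, -2.5100347517704652e-01, 8.0007274940739515e-01,
    5.4486773725807736e-01, 2.5100347517704652e-01, -8.0007274940739515e-01,
    -5.4486773725807736e-01, -2.5100347517704652e-01, 8.0007274940739515e-01,
    5.4486773725807736e-01, -2.5100347517704652e-01, -8.0007274940739515e-01,
    -5.4486773725807736e-01, 2.5100347517704652e-01, -8.0007274940739515e-01,
    -5.4486773725807736e-01, -2.5100347517704652e-01, -8.0007274940739515e-01,
    5.4486773725807736e-01, 8.0007274940739515e-01, 2.5100347517704652e-01,
    -5.4486773725807736e-01, 8.0007274940739515e-01, 2.5100347517704652e-01,
    5.4486773725807736e-01, -8.0007274940739515e-01, 2.5100347517704652e-01,
    5.4486773725807736e-01, 8.0007274940739515e-01, -2.5100347517704652e-01,
    -5.4486773725807736e-01, -8.0007274940739515e-01, 2.5100347517704652e-01,
    5.4486773725807736e-01, -8.0007274940739515e-01, -2.5100347517704652e-01,
    -5.4486773725807736e-01, 8.0007274940739515e-01, -2.5100347517704652e-01,
    -5.4486773725807736e-01, -8.0007274940739515e-01, -2.5100347517704652e-01,
    2.5100347517704652e-01, 5.4486773725807736e-01, 8.0007274940739515e-01,
    -2.5100347517704652e-01, 5.4486773725807736e-01, 8.0007274940739515e-01,
    2.5100347517704652e-01, -5.4486773725807736e-01, 8.0007274940739515e-01,
    2.5100347517704652e-01, 5.4486773725807736e-01, -8.0007274940739515e-01,
    -2.5100347517704652e-01, -5.4486773725807736e-01, 8.0007274940739515e-01,
    2.5100347517704652e-01, -5.4486773725807736e-01, -8.0007274940739515e-01,
    -2.5100347517704652e-01, 5.4486773725807736e-01, -8.0007274940739515e-01,
    -2.5100347517704652e-01, -5.4486773725807736e-01, -8.0007274940739515e-01,
    8.0007274940739515e-01, 5.4486773725807736e-01, 2.5100347517704652e-01,
    -8.0007274940739515e-01, 5.4486773725807736e-01, 2.5100347517704652e-01,
    8.0007274940739515e-01, -5.4486773725807736e-01, 2.5100347517704652e-01,
    8.0007274940739515e-01, 5.4486773725807736e-01, -2.5100347517704652e-01,
    -8.0007274940739515e-01, -5.4486773725807736e-01, 2.5100347517704652e-01,
    8.0007274940739515e-01, -5.4486773725807736e-01, -2.5100347517704652e-01,
    -8.0007274940739515e-01, 5.4486773725807736e-01, -2.5100347517704652e-01,
    -8.0007274940739515e-01, -5.4486773725807736e-01, -2.5100347517704652e-01,
    1.2335485325833270e-01, 4.1277240831685308e-01, 9.0244252953300041e-01,
    -1.2335485325833270e-01, 4.1277240831685308e-01, 9.0244252953300041e-01,
    1.2335485325833270e-01, -4.1277240831685308e-01, 9.0244252953300041e-01,
    1.2335485325833270e-01, 4.1277240831685308e-01, -9.0244252953300041e-01,
    -1.2335485325833270e-01, -4.1277240831685308e-01, 9.0244252953300041e-01,
    1.2335485325833270e-01, -4.1277240831685308e-01, -9.0244252953300041e-01,
    -1.2335485325833270e-01, 4.1277240831685308e-01, -9.0244252953300041e-01,
    -1.2335485325833270e-01, -4.1277240831685308e-01, -9.0244252953300041e-01,
    4.1277240831685308e-01, 1.2335485325833270e-01, 9.0244252953300041e-01,
    -4.1277240831685308e-01, 1.2335485325833270e-01, 9.0244252953300041e-01,
    4.1277240831685308e-01, -1.2335485325833270e-01, 9.0244252953300041e-01,
    4.1277240831685308e-01, 1.2335485325833270e-01, -9.0244252953300041e-01,
    -4.1277240831685308e-01, -1.2335485325833270e-01, 9.0244252953300041e-01,
    4.1277240831685308e-01, -1.2335485325833270e-01, -9.0244252953300041e-01,
    -4.1277240831685308e-01, 1.2335485325833270e-01, -9.0244252953300041e-01,
    -4.1277240831685308e-01, -1.2335485325833270e-01, -9.0244252953300041e-01,
    9.0244252953300041e-01, 1.2335485325833270e-01, 4.1277240831685308e-01,
    -9.0244252953300041e-01, 1.2335485325833270e-01, 4.1277240831685308e-01,
    9.0244252953300041e-01, -1.2335485325833270e-01, 4.1277240831685308e-01,
    9.0244252953300041e-01, 1.2335485325833270e-01, -4.1277240831685308e-01,
    -9.0244252953300041e-01, -1.2335485325833270e-01, 4.1277240831685308e-01,
    9.0244252953300041e-01, -1.2335485325833270e-01, -4.1277240831685308e-01,
    -9.0244252953300041e-01, 1.2335485325833270e-01, -4.1277240831685308e-01,
    -9.0244252953300041e-01, -1.2335485325833270e-01, -4.1277240831685308e-01,
    9.0244252953300041e-01, 4.1277240831685308e-01, 1.2335485325833270e-01,
    -9.0244252953300041e-01, 4.1277240831685308e-01, 1.2335485325833270e-01,
    9.0244252953300041e-01, -4.1277240831685308e-01, 1.2335485325833270e-01,
    9.0244252953300041e-01, 4.1277240831685308e-01, -1.2335485325833270e-01,
    -9.0244252953300041e-01, -4.1277240831685308e-01, 1.2335485325833270e-01,
    9.0244252953300041e-01, -4.1277240831685308e-01, -1.2335485325833270e-01,
    -9.0244252953300041e-01, 4.1277240831685308e-01, -1.2335485325833270e-01,
    -9.0244252953300041e-01, -4.1277240831685308e-01, -1.2335485325833270e-01,
    1.2335485325833270e-01, 9.0244252953300041e-01, 4.1277240831685308e-01,
    -1.2335485325833270e-01, 9.0244252953300041e-01, 4.1277240831685308e-01,
    1.2335485325833270e-01, -9.0244252953300041e-01, 4.1277240831685308e-01,
    1.2335485325833270e-01, 9.0244252953300041e-01, -4.1277240831685308e-01,
    -1.2335485325833270e-01, -9.0244252953300041e-01, 4.1277240831685308e-01,
    1.2335485325833270e-01, -9.0244252953300041e-01, -4.1277240831685308e-01,
    -1.2335485325833270e-01, 9.0244252953300041e-01, -4.1277240831685308e-01,
    -1.2335485325833270e-01, -9.0244252953300041e-01, -4.1277240831685308e-01,
    4.1277240831685308e-01, 9.0244252953300041e-01, 1.2335485325833270e-01,
    -4.1277240831685308e-01, 9.0244252953300041e-01, 1.2335485325833270e-01,
    4.1277240831685308e-01, -9.0244252953300041e-01, 1.2335485325833270e-01,
    4.1277240831685308e-01, 9.0244252953300041e-01, -1.2335485325833270e-01,
    -4.1277240831685308e-01, -9.0244252953300041e-01, 1.2335485325833270e-01,
    4.1277240831685308e-01, -9.0244252953300041e-01, -1.2335485325833270e-01,
    -4.1277240831685308e-01, 9.0244252953300041e-01, -1.2335485325833270e-01,
    -4.1277240831685308e-01, -9.0244252953300041e-01, -1.2335485325833270e-01
  ), ncol = 3L, byrow = TRUE),
  w = c(
    8.5459117251281483e-04, 8.5459117251281483e-04, 8.5459117251281483e-04, 8.5459117251281483e-04,
    8.5459117251281483e-04, 8.5459117251281483e-04, 3.5991192850255709e-03, 3.5991192850255709e-03,
    3.5991192850255709e-03, 3.5991192850255709e-03, 3.5991192850255709e-03, 3.5991192850255709e-03,
    3.5991192850255709e-03, 3.5991192850255709e-03, 3.4497884243058830e-03, 3.4497884243058830e-03,
    3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03,
    3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03,
    3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03,
    3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03,
    3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03, 3.4497884243058830e-03,
    3.4497884243058830e-03, 3.4497884243058830e-03, 3.6048226014198819e-03, 3.6048226014198819e-03,
    3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03,
    3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03,
    3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03,
    3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03,
    3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03, 3.6048226014198819e-03,
    3.6048226014198819e-03, 3.6048226014198819e-03, 3.5767296617433670e-03, 3.5767296617433670e-03,
    3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03,
    3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03,
    3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03,
    3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03,
    3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03, 3.5767296617433670e-03,
    3.5767296617433670e-03, 3.5767296617433670e-03, 2.3521014136891642e-03, 2.3521014136891642e-03,
    2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03,
    2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03,
    2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03,
    2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03,
    2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03, 2.3521014136891642e-03,
    2.3521014136891642e-03, 2.3521014136891642e-03, 3.1089531224136749e-03, 3.1089531224136749e-03,
    3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03,
    3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03,
    3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03,
    3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03,
    3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03, 3.1089531224136749e-03,
    3.1089531224136749e-03, 3.1089531224136749e-03, 3.6500458076772551e-03, 3.6500458076772551e-03,
    3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03,
    3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03,
    3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03,
    3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03,
    3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03, 3.6500458076772551e-03,
    3.6500458076772551e-03, 3.6500458076772551e-03, 2.9823449631718041e-03, 2.9823449631718041e-03,
    2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03,
    2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03,
    2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03,
    2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03,
    2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03, 2.9823449631718041e-03,
    2.9823449631718041e-03, 2.9823449631718041e-03, 3.6008209322164601e-03, 3.6008209322164601e-03,
    3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03,
    3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03,
    3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03,
    3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03,
    3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03, 3.6008209322164601e-03,
    3.6008209322164601e-03, 3.6008209322164601e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03, 3.5715405542733870e-03,
    3.5715405542733870e-03, 3.5715405542733870e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03, 3.3923122050061698e-03,
    3.3923122050061698e-03, 3.3923122050061698e-03
  ))
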