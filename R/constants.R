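# Atomic constants shared by the mass, fragment and isotope engines.
#
# Monoisotopic masses are CODATA/AME exact masses of the lightest isotope.
# Average masses use the conventional standard atomic weights that synthetic
# oligonucleotide vendors and MS software have historically used; these
# reproduce printed average masses of ~33 kDa guides to better than 0.02 Da.

.ELEMENTS <- c("C", "H", "N", "O", "P", "S")

.MONO_MASS <- c(
  C = 12.0,
  H = 1.007825031898,
  N = 14.003074004,
  O = 15.994914619,
  P = 30.973761998,
  S = 31.972071174
)

.AVG_MASS <- c(
  C = 12.011,
  H = 1.00794,
  N = 14.00674,
  O = 15.9994,
  P = 30.973762,
  S = 32.066
)

# Natural isotope vectors: nucleon offset from the lightest isotope, exact
# mass, and abundance (IUPAC representative values).
.ISOTOPES <- list(
  C = list(offset = c(0L, 1L),
           mass = c(12.0, 13.003354835),
           abundance = c(0.9893, 0.0107)),
  H = list(offset = c(0L, 1L),
           mass = c(1.007825031898, 2.014101778),
           abundance = c(0.999885, 0.000115)),
  N = list(offset = c(0L, 1L),
           mass = c(14.003074004, 15.000108899),
           abundance = c(0.99636, 0.00364)),
  O = list(offset = c(0L, 1L, 2L),
           mass = c(15.994914619, 16.999131757, 17.999159613),
           abundance = c(0.99757, 0.00038, 0.00205)),
  P = list(offset = 0L,
           mass = 30.973761998,
           abundance = 1.0),
  S = list(offset = c(0L, 1L, 2L, 4L),
           mass = c(31.972071174, 32.971458910, 33.967867012, 35.967080699),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Mass of a proton; subtracted per charge for [M - zH]^z- ions (electron
# bookkeeping folded into the constant).
.PROTON_MASS <- 1.007276

# Mean spacing between adjacent isotopologues of a singly charged ion, Da.
.ISOTOPE_SPACING <- 1.00336
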