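# Orthonormal scaling (low-pass reconstruction) filters for the supported
# mother wavelets. The three companion filters follow from the standard
# quadrature-mirror relations, so only the scaling filter is tabulated.

#' Mother wavelets available for denoising
#'
#' Character vector of the supported mother-wavelet names: Haar,
#' Daubechies 2/4/6, Symlets 2/4/6 and Coiflets 2/4/5.
#'
#' @export
MU_WAVELETS <- c("haar", "db2", "db4", "db6", "sym2", "sym4", "sym6", "coif2", "coif4", "coif5")

.scaling_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589, -0.027983769416859854,
    -0.18703481171909309, 0.030841381835560764, 0.0328830116668852, -0.010597401785069032),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954, 0.31525035170919763,
    -0.22626469396543983, -0.12976686756726194, 0.09750160558732304, 0.027522865530305727,
    -0.03158203931748603, 0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  sym2 = c(0.48296291314469025, 0.836516303737469, 0.22414386804185735, -0.12940952255092145),
  sym4 = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722, 0.29785779560527736,
    0.8037387518059161, 0.49761866763201545, -0.02963552764599851, -0.07576571478927333),
  sym6 = c(-0.007800708325034148, 0.0017677118642428036, 0.04472490177066578, -0.021060292512300564,
    -0.07263752278646252, 0.3379294217276218, 0.787641141030194, 0.4910559419267466,
    -0.048311742585633, -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
  coif2 = c(0.01638733646320364, -0.04146493678687178, -0.0673725547237256, 0.3861100668227629,
    0.8127236354494135, 0.4170051844232391, -0.07648859907828076, -0.05943441864643109,
    0.02368017194684777, 0.005611434819368834, -0.0018232088709110323, -0.000720549445520347),
  coif4 = c(0.000892313902537003, -0.001629492425226786, -0.007346167936268051, 0.01606894713157503,
    0.02668230466960483, -0.08126671024919373, -0.05607731960356926, 0.41530842700068227,
    0.7822389344242826, 0.43438603311435653, -0.06662747236681717, -0.09622042453595264,
    0.03933442260558915, 0.02508225333794961, -0.015211728187697211, -0.0056582838001308835,
    0.0037514346971460866, 0.0012665610789256603, -0.0005890202246332165, -0.0002599743371222568,
    6.233885431278719e-05, 3.1229861599195265e-05, -3.259647940030751e-06, -1.7849909144933469e-06),
  coif5 = c(-0.000212081862067494, 0.0003585777411617577, 0.0021782943778456947, -0.00415931262757864,
    -0.010131584846900276, 0.023408322118927783, 0.028169744270532353, -0.09192158806008609,
    -0.052046670253554764, 0.42157126673075435, 0.7742936228603274, 0.4379823066591634,
    -0.06203775157498196, -0.10556315130733723, 0.041287530472117834, 0.032674799467057355,
    -0.019758391600965465, -0.009159507338676163, 0.006761520220620417, 0.0024315754425382886,
    -0.0016616273039298788, -0.0006375589261258812, 0.0003018579416682448, 0.00014035632812373243,
    -4.12198619242655e-05, -2.1270221672515614e-05, 3.7007277113394796e-06, 2.0612203985788783e-06,
    -1.6237995172048338e-07, -9.604010112767894e-08)
)

#' Filter bank for a mother wavelet
#'
#' Returns the four orthonormal filters (decomposition and reconstruction,
#' low- and high-pass) that define the discrete wavelet transform for one
#' of the supported mother wavelets.
#'
#' @param wavelet One of [MU_WAVELETS].
#' @return List with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`
#'   (numeric filter taps) and `length` (number of taps).
#' @export
wavelet_filters <- function(wavelet) {
  if (!is.character(wavelet) || length(wavelet) != 1L ||
      !wavelet %in% MU_WAVELETS) {
    stop("unsupported wavelet: ", paste(wavelet, collapse = ", "),
         " (supported: ", paste(MU_WAVELETS, collapse = ", "), ")")
  }
  h <- .scaling_filters[[wavelet]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)  # quadrature mirror
  list(dec_lo = rev(h), dec_hi = rev(g), rec_lo = h, rec_hi = g,
       length = L)
}
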