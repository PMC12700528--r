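// CRC-32 (IEEE 802.3) for the stored-entry zip writer behind the NPZ codec.
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_crc32")]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320U ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFU;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFU] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFU);
}
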