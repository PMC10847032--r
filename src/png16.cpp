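// Minimal 16-bit grayscale PNG writer (zlib-compressed, filter type 0).
// Reading is done in R via png::readPNG, which handles 16-bit natively;
// only the writer needs to live here.
#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>
#include <stdexcept>

using namespace Rcpp;

namespace {

void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

void write_chunk(FILE* fp, const char* type,
                 const std::vector<unsigned char>& data) {
  std::vector<unsigned char> hdr;
  put_u32(hdr, (uint32_t)data.size());
  fwrite(hdr.data(), 1, 4, fp);
  unsigned char t[4] = {(unsigned char)type[0], (unsigned char)type[1],
                        (unsigned char)type[2], (unsigned char)type[3]};
  fwrite(t, 1, 4, fp);
  if (!data.empty()) fwrite(data.data(), 1, data.size(), fp);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, t, 4);
  if (!data.empty()) crc = crc32(crc, data.data(), (uInt)data.size());
  std::vector<unsigned char> c;
  put_u32(c, (uint32_t)crc);
  fwrite(c.data(), 1, 4, fp);
}

} // namespace

// img: integer matrix (height x width), values clamped to [0, 65535]
// [[Rcpp::export(name = ".cpp_write_png16")]]
void cpp_write_png16(IntegerMatrix img, std::string path) {
  int h = img.nrow(), w = img.ncol();
  std::vector<unsigned char> raw((size_t)h * (1 + 2 * (size_t)w));
  size_t k = 0;
  for (int r = 0; r < h; ++r) {
    raw[k++] = 0;  // filter: none
    for (int c = 0; c < w; ++c) {
      int val = img(r, c);
      if (val < 0 || val == NA_INTEGER) val = 0;
      if (val > 65535) val = 65535;
      raw[k++] = (val >> 8) & 0xff;
      raw[k++] = val & 0xff;
    }
  }
  uLongf bound = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(bound);
  if (compress2(comp.data(), &bound, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(bound);

  FILE* fp = std::fopen(path.c_str(), "wb");
  if (!fp) stop("cannot open '%s' for writing", path.c_str());
  unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, fp);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)w);
  put_u32(ihdr, (uint32_t)h);
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // grayscale
  ihdr.push_back(0);   // compression
  ihdr.push_back(0);   // filter
  ihdr.push_back(0);   // no interlace
  write_chunk(fp, "IHDR", ihdr);
  write_chunk(fp, "IDAT", comp);
  write_chunk(fp, "IEND", std::vector<unsigned char>());
  std::fclose(fp);
}
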