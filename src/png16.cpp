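// Minimal 16-bit grayscale PNG encoder (the installed readers handle 16-bit
// PNG input but can only write 8-bit). Uses the system zlib for the IDAT
// deflate stream and its crc32 for chunk checksums.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static void write_chunk(FILE* f, const char type[4],
                        const unsigned char* data, uint32_t len) {
  std::vector<unsigned char> hdr;
  put_u32(hdr, len);
  fwrite(hdr.data(), 1, 4, f);
  fwrite(type, 1, 4, f);
  if (len) fwrite(data, 1, len, f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, reinterpret_cast<const Bytef*>(type), 4);
  if (len) crc = crc32(crc, data, len);
  std::vector<unsigned char> tail;
  put_u32(tail, (uint32_t)crc);
  fwrite(tail.data(), 1, 4, f);
}

// img: H x W integer matrix with values in [0, 65535]
// [[Rcpp::export]]
void write_png16(std::string path, IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<unsigned char> raw((size_t)H * (1 + (size_t)W * 2));
  size_t pos = 0;
  for (int i = 0; i < H; ++i) {
    raw[pos++] = 0;  // filter type none
    for (int j = 0; j < W; ++j) {
      int v = img(i, j);
      if (v < 0 || v > 65535) stop("pixel value outside [0, 65535]");
      raw[pos++] = (v >> 8) & 0xff;
      raw[pos++] = v & 0xff;
    }
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 9) != Z_OK)
    stop("zlib compression failed");

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // grayscale
  ihdr.push_back(0);   // deflate
  ihdr.push_back(0);   // adaptive filtering
  ihdr.push_back(0);   // no interlace
  write_chunk(f, "IHDR", ihdr.data(), (uint32_t)ihdr.size());
  write_chunk(f, "IDAT", comp.data(), (uint32_t)clen);
  write_chunk(f, "IEND", nullptr, 0);
  std::fclose(f);
}
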