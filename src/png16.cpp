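// Minimal 16-bit grayscale PNG encoder. The zlib stream uses stored
// (uncompressed) deflate blocks, so no compression library is required;
// CRC32 and Adler32 are computed directly. Reading is done in R with
// png::readPNG, which handles 16-bit images.
#include <Rcpp.h>
#include <cstdio>
#include <vector>

using Rcpp::IntegerMatrix;

namespace {

uint32_t crc_table[256];
bool crc_ready = false;

void make_crc_table() {
  for (uint32_t n = 0; n < 256; ++n) {
    uint32_t c = n;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xedb88320U ^ (c >> 1) : c >> 1;
    crc_table[n] = c;
  }
  crc_ready = true;
}

uint32_t crc32_buf(const std::vector<unsigned char>& buf) {
  if (!crc_ready) make_crc_table();
  uint32_t c = 0xffffffffU;
  for (unsigned char b : buf) c = crc_table[(c ^ b) & 0xff] ^ (c >> 8);
  return c ^ 0xffffffffU;
}

uint32_t adler32_buf(const std::vector<unsigned char>& buf) {
  uint32_t a = 1, b = 0;
  for (unsigned char ch : buf) {
    a = (a + ch) % 65521;
    b = (b + a) % 65521;
  }
  return (b << 16) | a;
}

void push_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

void write_chunk(FILE* f, const char type[4],
                 const std::vector<unsigned char>& data) {
  std::vector<unsigned char> payload(type, type + 4);
  payload.insert(payload.end(), data.begin(), data.end());
  std::vector<unsigned char> lenb;
  push_u32(lenb, (uint32_t)data.size());
  fwrite(lenb.data(), 1, 4, f);
  fwrite(payload.data(), 1, payload.size(), f);
  std::vector<unsigned char> crcb;
  push_u32(crcb, crc32_buf(payload));
  fwrite(crcb.data(), 1, 4, f);
}

} // namespace

// values: H x W matrix of integers in [0, 65535]
// [[Rcpp::export]]
void cpp_write_png16(IntegerMatrix values, std::string path) {
  const int H = values.nrow(), W = values.ncol();
  // raw scanlines: filter byte 0 + big-endian 16-bit samples
  std::vector<unsigned char> raw;
  raw.reserve((size_t)H * (1 + 2 * W));
  for (int r = 0; r < H; ++r) {
    raw.push_back(0);
    for (int c = 0; c < W; ++c) {
      int v = values(r, c);
      if (v < 0 || v > 65535) Rcpp::stop("pixel value out of 16-bit range");
      raw.push_back((v >> 8) & 0xff);
      raw.push_back(v & 0xff);
    }
  }
  // zlib stream: header + stored deflate blocks + adler32
  std::vector<unsigned char> z;
  z.push_back(0x78);
  z.push_back(0x01);
  size_t pos = 0;
  while (pos < raw.size()) {
    const size_t n = std::min<size_t>(65535, raw.size() - pos);
    const bool final_block = (pos + n == raw.size());
    z.push_back(final_block ? 1 : 0);
    z.push_back(n & 0xff);
    z.push_back((n >> 8) & 0xff);
    z.push_back(~n & 0xff);
    z.push_back((~n >> 8) & 0xff);
    z.insert(z.end(), raw.begin() + pos, raw.begin() + pos + n);
    pos += n;
  }
  push_u32(z, adler32_buf(raw));

  FILE* f = fopen(path.c_str(), "wb");
  if (!f) Rcpp::stop("cannot open '%s' for writing", path.c_str());
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  push_u32(ihdr, (uint32_t)W);
  push_u32(ihdr, (uint32_t)H);
  ihdr.push_back(16); // bit depth
  ihdr.push_back(0);  // grayscale
  ihdr.push_back(0);  // deflate
  ihdr.push_back(0);  // adaptive filtering
  ihdr.push_back(0);  // no interlace
  write_chunk(f, "IHDR", ihdr);
  write_chunk(f, "IDAT", z);
  write_chunk(f, "IEND", {});
  fclose(f);
}
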