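// Second compression stage: standard xz/LZMA2 streams via liblzma.
// threads == 1 encodes a single block with the configured dictionary
// (best ratio); threads > 1 uses the multi-threaded encoder, which splits
// the stream into independent blocks and can cost some ratio.
#include <Rcpp.h>
#include <lzma.h>

using namespace Rcpp;

static RawVector run_encoder(lzma_stream* strm, RawVector data) {
  std::vector<uint8_t> out;
  out.resize(data.size() / 2 + 4096);
  strm->next_in = data.size() ? (const uint8_t*)RAW(data) : nullptr;
  strm->avail_in = data.size();
  strm->next_out = out.data();
  strm->avail_out = out.size();
  lzma_ret ret;
  for (;;) {
    ret = lzma_code(strm, LZMA_FINISH);
    if (ret == LZMA_STREAM_END) break;
    if (ret != LZMA_OK) {
      lzma_end(strm);
      stop("LZMA encoder failed (code %d)", (int)ret);
    }
    if (strm->avail_out == 0) {
      size_t used = out.size();
      out.resize(out.size() * 2);
      strm->next_out = out.data() + used;
      strm->avail_out = out.size() - used;
    }
  }
  size_t n = out.size() - strm->avail_out;
  lzma_end(strm);
  RawVector res(n);
  if (n) memcpy(RAW(res), out.data(), n);
  return res;
}

// [[Rcpp::export(rng = false)]]
RawVector rp_xz_compress(RawVector data, int preset, double dict_bytes,
                         int threads, double block_bytes) {
  if (preset < 0 || preset > 9) stop("preset must be in 0..9");
  if (threads < 1) stop("threads must be >= 1");
  lzma_options_lzma opt;
  if (lzma_lzma_preset(&opt, (uint32_t)preset)) stop("invalid LZMA preset");
  if (dict_bytes > 0) {
    if (dict_bytes < 4096) stop("dictionary size must be >= 4 KiB");
    opt.dict_size = (uint32_t)dict_bytes;
  }
  lzma_filter filters[2];
  filters[0].id = LZMA_FILTER_LZMA2;
  filters[0].options = &opt;
  filters[1].id = LZMA_VLI_UNKNOWN;

  lzma_stream strm = LZMA_STREAM_INIT;
  lzma_ret ret;
  if (threads == 1) {
    ret = lzma_stream_encoder(&strm, filters, LZMA_CHECK_CRC32);
  } else {
    lzma_mt mt;
    memset(&mt, 0, sizeof(mt));
    mt.threads = (uint32_t)threads;
    mt.block_size = block_bytes > 0 ? (uint64_t)block_bytes : 0;
    mt.filters = filters;
    mt.check = LZMA_CHECK_CRC32;
    ret = lzma_stream_encoder_mt(&strm, &mt);
  }
  if (ret != LZMA_OK) stop("failed to initialize LZMA encoder (code %d)", (int)ret);
  return run_encoder(&strm, data);
}

// [[Rcpp::export(rng = false)]]
RawVector rp_xz_decompress(RawVector data) {
  lzma_stream strm = LZMA_STREAM_INIT;
  lzma_ret ret = lzma_stream_decoder(&strm, UINT64_MAX, LZMA_CONCATENATED);
  if (ret != LZMA_OK) stop("failed to initialize LZMA decoder (code %d)", (int)ret);
  std::vector<uint8_t> out;
  out.resize(data.size() * 3 + 4096);
  strm.next_in = data.size() ? (const uint8_t*)RAW(data) : nullptr;
  strm.avail_in = data.size();
  strm.next_out = out.data();
  strm.avail_out = out.size();
  for (;;) {
    ret = lzma_code(&strm, LZMA_FINISH);
    if (ret == LZMA_STREAM_END) break;
    if (ret != LZMA_OK) {
      lzma_end(&strm);
      stop("corrupt or truncated xz stream (code %d)", (int)ret);
    }
    if (strm.avail_out == 0) {
      size_t used = out.size();
      out.resize(out.size() * 2);
      strm.next_out = out.data() + used;
      strm.avail_out = out.size() - used;
    }
  }
  size_t n = out.size() - strm.avail_out;
  lzma_end(&strm);
  RawVector res(n);
  if (n) memcpy(RAW(res), out.data(), n);
  return res;
}
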