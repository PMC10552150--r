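# liblzma headers/libs come from the system xz-utils development package;
# -idirafter keeps the toolchain's own include order intact.
PKG_CPPFLAGS = -idirafter /usr/include
PKG_LIBS = -L/usr/lib/x86_64-linux-gnu -llzma -lz
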