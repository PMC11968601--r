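# Default denoising pattern list, applied in order (regular expressions).
# Newlines are preserved (structured-report renderings are line-oriented).
# Versioned with the package; edit or extend to match local report noise.
- pattern: "<[^>]*>"            # markup tags
  replacement: " "
- pattern: "[*_#~`^|\\\\]+"     # stray markup characters
  replacement: ""
- pattern: "[^[:print:]\\n]"    # non-printing characters (newline kept)
  replacement: " "
- pattern: "([.,;:!?])\\1+"     # repeated punctuation collapsed to one
  replacement: "\\1"
- pattern: "[ \\t]+"            # duplicated horizontal whitespace
  replacement: " "
- pattern: " ?\\n ?"            # spaces hugging a line break
  replacement: "\n"
- pattern: "^[ \\n]+|[ \\n]+$"  # leading/trailing blank space
  replacement: ""
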